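test_that("generator matches hand-built matrices and conserves rows", {
  g2 <- build_generator(two_state(1, 3))
  expect_equal(as.matrix(g2$Q), matrix(c(-1, 3, 1, -3), 2, 2),
               ignore_attr = TRUE)

  # SISa with N = 2: tridiagonal with propensities from coarse_propensities
  m <- build_sisa(a = 0.05, beta = 0.4, g = 0.3, N0 = 2, omega = 1)
  gen <- build_generator(m)
  Q <- as.matrix(gen$Q)
  expect_equal(dim(Q), c(3, 3))
  for (n in 0:2) {
    pr <- coarse_propensities(m, n)
    if (n < 2) expect_equal(Q[n + 1, n + 2], pr$birth)
    if (n > 0) expect_equal(Q[n + 1, n], pr$death)
  }
  expect_equal(Q[1, 3], 0) # only single-step moves
  expect_lt(max(abs(Matrix::rowSums(gen$Q))), 1e-12 * max(abs(gen$Q@x)))

  expect_error(build_generator(resize(build_sisa(), 1), cap = 10), "cap")
  expect_true(is_irreducible(gen))
})

test_that("stationary solves agree with closed forms and the birth-death oracle", {
  expect_equal(solve_stationary(build_generator(two_state(1, 3)))$p,
               c(0.75, 0.25), tolerance = 1e-12)

  # zero coupling: Binomial(N, a / (a + b))
  m <- zero_coupling(12, a = 0.3, b = 0.9)
  p <- solve_stationary(build_generator(m))$p
  expect_lt(total_variation(p, dbinom(0:12, 12, 0.25)), 1e-12)

  # both solver routes match the closed-form product oracle
  gen <- build_generator(resize(build_sisa(), 0.2))
  rts <- bd_rates(resize(build_sisa(), 0.2))
  oracle <- bd_stationary_closedform(rts$birth, rts$death)$p
  expect_lt(total_variation(solve_stationary(gen, method = "gth")$p, oracle), 1e-12)
  expect_lt(total_variation(solve_stationary(gen, method = "sparse")$p, oracle), 1e-9)

  # GTH retains relative accuracy deep in the tails (supercritical SISa)
  gen2 <- build_generator(resize(build_sisa(), 0.8))
  p2 <- solve_stationary(gen2)$p
  o2 <- bd_stationary_closedform(bd_rates(resize(build_sisa(), 0.8))$birth,
                                 bd_rates(resize(build_sisa(), 0.8))$death)$p
  expect_true(all(p2 > 0))
  expect_lt(max(abs(log(p2) - log(o2))), 1e-8)
})

test_that("bd_stationary_closedform handles canonical cases", {
  expect_equal(bd_stationary_closedform(rep(2, 5), rep(2, 5))$p, rep(1 / 6, 6))
  expect_equal(bd_stationary_closedform(1, 3)$p, c(0.75, 0.25))
  # N = 2 exchangeable nodes, a = b: Binomial(2, 1/2)
  m <- zero_coupling(2, a = 1, b = 1)
  rts <- bd_rates(m)
  expect_equal(bd_stationary_closedform(rts$birth, rts$death)$p,
               c(0.25, 0.5, 0.25))
  expect_error(bd_stationary_closedform(c(1, 0), c(1, 1)), "positive")
})

test_that("transient solve reproduces relaxation and reaches the ergodic limit", {
  gen <- build_generator(two_state(1, 3))
  sols <- solve_transient(gen, c(0), c(0, 0.05, 0.3, 1, 4))
  expect_equal(sols[[1]]$p, c(1, 0)) # t = 0 identity
  ts <- c(0, 0.05, 0.3, 1, 4)
  for (i in seq_along(ts)) {
    expect_equal(sols[[i]]$p[2], 0.25 * (1 - exp(-4 * ts[i])), tolerance = 1e-9)
    expect_equal(sum(sols[[i]]$p), 1, tolerance = 1e-12)
  }

  # multi-block: mass conserved, long-time limit = stationary law
  gen2 <- build_generator(two_block_asym())
  out <- solve_transient(gen2, c(0, 0), c(0.5, 2, 60))
  for (o in out) expect_equal(sum(o$p), 1, tolerance = 1e-8)
  pst <- solve_stationary(gen2)
  expect_lt(total_variation(out[[3]]$p, pst$p), 1e-6)
})

test_that("mean first passage matches hand formulas and a dense solve", {
  gen <- build_generator(two_state(2, 5))
  expect_equal(mean_first_passage(gen, 0, 0), 0)
  expect_equal(mean_first_passage(gen, 0, 1), 1 / 2) # 1 / lambda_0

  # 3-state birth-death: tau_0 = 1/l0 + 1/l1 + m1/(l0 l1)
  m <- zero_coupling(2, a = 0.7, b = 1.3)
  gen3 <- build_generator(m)
  l0 <- 2 * 0.7; l1 <- 0.7; mu1 <- 1.3
  expect_equal(mean_first_passage(gen3, 0, 2),
               1 / l0 + 1 / l1 + mu1 / (l0 * l1), tolerance = 1e-10)

  # brute-force dense linear solve on a 2-D lattice
  m2 <- two_block_asym(c(2, 3))
  gen2 <- build_generator(m2)
  target <- c(2, 3)
  it <- state_to_index(gen2$space, target)
  keep <- setdiff(seq_len(gen2$space$n_states), it)
  Qd <- as.matrix(gen2$Q)
  tau_dense <- solve(Qd[keep, keep], rep(-1, length(keep)))
  i0 <- state_to_index(gen2$space, c(0, 0))
  expect_equal(mean_first_passage(gen2, c(0, 0), target),
               tau_dense[match(i0, keep)], tolerance = 1e-10)

  em <- coarse_lmn(sizes = 2, block_weights = matrix(0), leak_on = 0,
                   leak_off = 1, gain_on = "zero")
  expect_error(mean_first_passage(build_generator(em), 0, 2), "reachable")
})

test_that("state exit times follow the holding-time law", {
  m <- resize(build_sisa(), 0.25) # N = 50, a = 1e-4
  expect_equal(state_exit_time(m, 0), 1 / (50 * 1e-4)) # 200 days
  expect_equal(state_exit_time(two_state(1, 3), 1), 1 / 3)
  ab <- coarse_lmn(sizes = 1, block_weights = matrix(0), leak_on = 0,
                   leak_off = 1, gain_on = "zero")
  et <- state_exit_time(ab, 0)
  expect_true(is.infinite(et))
  expect_true(attr(et, "absorbing"))
})

test_that("affinity vanishes in detailed balance and is positive off it", {
  gen <- build_generator(resize(build_sisa(), 0.1))
  pst <- solve_stationary(gen)
  expect_lt(max_abs_affinity(gen, pst), 1e-8) # 1-D birth-death: equilibrium

  gen2 <- build_generator(two_block_asym())
  pst2 <- solve_stationary(gen2)
  a_st <- max_abs_affinity(gen2, pst2)
  expect_gt(a_st, 1e-3) # genuine non-equilibrium steady state

  # transient affinity decays toward the stationary value
  out <- solve_transient(gen2, c(0, 0), c(0.3, 2, 50))
  a_t <- vapply(out, function(p) max_abs_affinity(gen2, p), numeric(1))
  expect_true(all(diff(a_t) < 0))
  expect_equal(a_t[3], a_st, tolerance = 1e-4)

  # a transition without reverse rate cannot form the log-ratio
  oneway <- coarse_lmn(sizes = 2, block_weights = matrix(0), leak_on = 0.5,
                       leak_off = 0, gain_on = "zero")
  g1 <- build_generator(oneway)
  pu <- lmnet:::.new_distribution(rep(1 / 3, 3), g1$space)
  expect_error(max_abs_affinity(g1, pu), "reverse")
})

test_that("distributions round-trip through TSV + sidecar", {
  gen <- build_generator(two_block_asym())
  p <- solve_stationary(gen)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(p, f)
  p2 <- read_distribution(f)
  expect_equal(p2$p, p$p)
  expect_identical(p2$space$sizes, p$space$sizes)
  expect_identical(p2$time, "stationary")
})
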