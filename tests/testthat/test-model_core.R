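test_that("net_input sums weighted active states plus external input", {
  W <- matrix(c(0, 1, 2,
                0, 0, 0,
                0, 0, 0), 3, 3, byrow = TRUE)
  m <- node_lmn(W, leak_on = 0.1, leak_off = 0.1, gain_on = "zero")
  expect_equal(net_input(m, c(0, 0, 0), 1), 0)
  expect_equal(net_input(m, c(1, 1, 1), 1), 3)

  W2 <- matrix(c(0, -1, 2, rep(0, 6)), 3, 3, byrow = TRUE)
  m2 <- node_lmn(W2, leak_on = 0.1, leak_off = 0.1, gain_on = "zero",
                 external_input = c(0.5, 0, 0))
  expect_equal(net_input(m2, c(0, 0, 1), 1), 2.5)

  expect_error(net_input(m, c(0, 2, 0), 1), "binary")
  expect_error(node_lmn(diag(2), 1, 1), "diagonal")
})

test_that("node propensities combine indicator, leak and gain", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  m <- node_lmn(W, leak_on = 0.1, leak_off = 0.2, gain_on = "zero")
  pr <- node_propensities(m, c(1, 0), 1)
  expect_equal(unname(pr["rate_on"]), 0)   # already active
  expect_gt(pr["rate_off"], 0)
  pr <- node_propensities(m, c(0, 0), 1)
  expect_equal(unname(pr["rate_off"]), 0)  # inactive
  expect_equal(unname(pr["rate_on"]), 0.1) # leak only (no active inputs)

  # additive leak + identity gain, hand evaluation
  m3 <- node_lmn(matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE),
                 leak_on = 0.01, leak_off = 0.2, gain_on = "identity")
  pr3 <- node_propensities(m3, c(0, 1), 1) # u = 0.5
  expect_equal(unname(pr3["rate_on"]), 0.51)
})

test_that("coarse graining aggregates block weights as N_l * w(k,l)", {
  # one block of 4 with uniform off-diagonal weight c
  cc <- 0.25
  W <- matrix(cc, 4, 4); diag(W) <- 0
  m <- node_lmn(W, leak_on = 0.3, leak_off = 0.7, gain_on = "tanh_plus")
  cm <- coarse_grain(m, list(1:4))
  expect_equal(cm$block_weights[1, 1], 4 * cc)
  # exact input of an inactive node with n active: c * n
  expect_equal(coarse_input(cm, 2), cc * 4 * (2 / 4))

  # two blocks (2, 3) with uniform cross-weights
  W2 <- matrix(0, 5, 5)
  W2[1:2, 3:5] <- 0.4          # block 1 <- block 2
  W2[3:5, 1:2] <- 0.1
  m2 <- node_lmn(W2, leak_on = rep(c(0.2, 0.5), c(2, 3)),
                 leak_off = 1, gain_on = "tanh_plus")
  cm2 <- coarse_grain(m2, list(1:2, 3:5))
  expect_equal(cm2$block_weights[1, 2], 3 * 0.4)
  expect_equal(cm2$block_weights[2, 1], 2 * 0.1)
  expect_equal(cm2$sizes, c(2L, 3L))

  # heterogeneous leak within a block is rejected, naming the block
  m3 <- node_lmn(W2, leak_on = c(0.2, 0.3, 0.5, 0.5, 0.5),
                 leak_off = 1, gain_on = "tanh_plus")
  expect_error(coarse_grain(m3, list(1:2, 3:5)), "block 1.*leak_on")
})

test_that("coarse propensities match the hand-evaluated SISa example", {
  # N = 100, a = 0.01, transmission 0.2, recovery 0.05, n = 50
  m <- build_sisa(a = 0.01, beta = 0.2, g = 0.05, N0 = 100, omega = 1)
  pr <- coarse_propensities(m, 50)
  expect_equal(pr$birth, 50 * (0.01 + 0.1)) # = 5.5
  expect_equal(pr$death, 2.5)
  expect_equal(coarse_propensities(m, 0)$birth, 100 * 0.01)
  expect_equal(coarse_propensities(m, 0)$death, 0)
  expect_equal(coarse_propensities(m, 100)$birth, 0) # saturation
  expect_error(coarse_propensities(m, 101), "counts")
})

test_that("resize rescales sizes deterministically and is invertible", {
  m <- build_sisa() # N0 = 200
  expect_identical(resize(m, network_size(m))$sizes, m$sizes)
  expect_identical(resize(m, 0.25)$sizes, 50L)

  nn <- build_nn(N0 = 150)
  expect_identical(resize(nn, 0.5)$sizes, c(38L, 38L)) # round-half-even of 37.5
  # round trip where rounding is exact
  m2 <- resize(m, 0.4)
  expect_identical(resize(resize(m2, 0.8), 0.4)$sizes, m2$sizes)
  expect_error(resize(nn, 0.001), "too small")
})

test_that("node-level and coarse propensities agree on homogeneous fixtures", {
  fixtures <- fixture_models(seed = 4, n = 6)
  for (fx in fixtures) {
    m <- fx$node; cm <- fx$coarse
    # random binary states, summed per block
    set.seed(99)
    for (rep in 1:5) {
      x <- rbinom(m$n_nodes, 1, 0.5)
      counts <- vapply(fx$blocks, function(p) sum(x[p]), numeric(1))
      pr <- coarse_propensities(cm, counts)
      for (k in seq_along(fx$blocks)) {
        rates <- vapply(fx$blocks[[k]], function(i) node_propensities(m, x, i),
                        numeric(2))
        bound <- abs(cm$block_weights[k, k]) / cm$sizes[k] + 1e-9
        # births exact (inactive nodes see exactly the coarse input);
        # deaths exact here because gain_off is zero in all fixtures
        expect_lt(abs(sum(rates["rate_on", ]) - pr$birth[k]), bound)
        expect_equal(sum(rates["rate_off", ]), pr$death[k], tolerance = 1e-12)
      }
    }
    # invariance under node relabeling within blocks
    perm <- unlist(lapply(fx$blocks, sample))
    inv <- order(perm)
    mp <- node_lmn(m$weights[perm, perm, drop = FALSE],
                   m$leak_on[perm], m$leak_off[perm],
                   m$gain_on[perm], m$gain_off[perm],
                   m$external_input[perm])
    cmp <- coarse_grain(mp, lapply(fx$blocks, function(p) match(p, perm)))
    expect_equal(cmp$block_weights, cm$block_weights, tolerance = 1e-12)
  }
})

test_that("model configs round-trip through JSON and YAML", {
  m <- build_nn(omega = 0.4)
  for (ext in c("json", "yaml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_lmn_config(m, f)
    m2 <- read_lmn_config(f)
    expect_identical(m2$sizes, m$sizes)
    expect_equal(m2$block_weights, m$block_weights)
    expect_equal(m2$leak_on, m$leak_on)
    expect_equal(m2$block_input, m$block_input)
    expect_identical(m2$gain_on, m$gain_on)
    expect_identical(m2$time_unit, m$time_unit)
    expect_equal(network_size(m2), network_size(m))
  }
})

test_that("gain registry validates and supports user registration", {
  expect_equal(gain_function("tanh_plus")(c(-1, 0, 0.5)),
               c(0, 0, tanh(0.5)))
  expect_error(gain_function("nope"), "unknown")
  register_gain("half", function(u) 0.5 * pmax(u, 0))
  expect_true("half" %in% list_gains())
  m <- coarse_lmn(sizes = 3, block_weights = matrix(1), leak_on = 0.1,
                  leak_off = 0.2, gain_on = "half")
  expect_equal(coarse_propensities(m, 3)$birth, 0)
  expect_equal(coarse_propensities(m, 1)$death, 0.2)
})
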