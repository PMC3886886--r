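# build a minimal trajectory by hand
mk_traj <- function(time, direction, N = 100, t_end = 10, block = NULL) {
  structure(list(time = time, block = block %||% rep(1L, length(time)),
                 direction = as.integer(direction), init = 0L,
                 final = 0L, t_end = t_end, seed = 0L, absorbing = FALSE,
                 sizes = as.integer(N), time_unit = "day"),
            class = "lmn_trajectory")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("threshold detector reproduces the hand-traced rule", {
  tr <- mk_traj(c(1, 2.5, 5, 5.5, 6, 7), c(1, -1, 1, 1, -1, -1))
  cat_ <- detect_threshold_avalanches(tr, 0.01)
  expect_equal(nrow(cat_), 2L)
  expect_equal(cat_$fractional_size, c(0.01, 0.02))
  expect_equal(cat_$duration, c(1.5, 2))
  expect_equal(attr(cat_, "rate"), 0.2) # 2 avalanches over 10 days

  # a trace that never reaches the threshold
  none <- detect_threshold_avalanches(mk_traj(c(1, 2), c(1, -1), N = 100), 0.05)
  expect_identical(nrow(none), 0L)
  expect_equal(attr(none, "rate"), 0)
  expect_error(detect_threshold_avalanches(tr, 0), "theta")
  expect_error(detect_threshold_avalanches(tr, 1.5), "theta")

  # conservation: activations inside avalanches + outside = all activations
  m <- resize(build_sisa(), 0.15)
  traj <- simulate_lmn(m, 5e4, seed = 8)
  cc <- detect_threshold_avalanches(traj, 0.05)
  inside <- sum(cc$activation_count)
  expect_lte(inside, attr(cc, "total_activations"))
  expect_identical(attr(cc, "total_activations"), sum(traj$direction == 1))

  # theta = 1/N: every activation lies inside an avalanche
  cc2 <- detect_threshold_avalanches(traj, 1 / sum(m$sizes))
  expect_identical(sum(cc2$activation_count), attr(cc2, "total_activations"))
})

test_that("lowering the threshold only merges or extends avalanches", {
  m <- resize(build_sisa(), 0.15)
  traj <- simulate_lmn(m, 1e5, seed = 13)
  hi <- detect_threshold_avalanches(traj, 0.08)
  lo <- detect_threshold_avalanches(traj, 0.02)
  expect_gt(nrow(hi), 3)
  # every high-threshold avalanche is contained in exactly one low-threshold
  # avalanche: lowering theta merges or extends, never splits
  for (j in seq_len(nrow(hi))) {
    k <- which(lo$start <= hi$start[j] & lo$end >= hi$end[j])
    expect_length(k, 1)
  }
})

test_that("size-distribution fit recovers an exact power law and flags non-power laws", {
  # counts n_j placed at geometric bin midpoints so that the log-binned
  # density lies exactly on a line of slope -1.5
  edges <- c(1e-4, 1e-2, 1, 100)
  mids <- sqrt(edges[-4] * edges[-1])
  # geometric bins have width prop. to the midpoint, so counts prop. to
  # mids^-0.5 give a binned density exactly prop. to mids^-1.5
  counts <- c(10000, 1000, 100)
  sizes <- rep(mids, counts)
  cat_ <- data.frame(fractional_size = sizes, truncated = FALSE)
  fit <- suppressWarnings( # lm flags the (intended) essentially perfect fit
    fit_size_distribution(cat_, s_range = c(1e-4, 100), bins_per_decade = 0.5))
  expect_equal(fit$slope, -1.5, tolerance = 1e-9)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-6)

  # exponential sizes are visibly worse than a matched power-law sample
  set.seed(31)
  n <- 5000
  pl <- 0.01 * (1 - runif(n))^(-1 / 0.5)          # tail exponent 1.5 density
  expo <- 0.01 + rexp(n, 1 / 0.05)
  f_pl <- fit_size_distribution(data.frame(fractional_size = pl),
                                s_range = c(0.01, 1), bins_per_decade = 10)
  f_ex <- fit_size_distribution(data.frame(fractional_size = expo),
                                s_range = c(0.01, 1), bins_per_decade = 10)
  expect_gt(f_pl$adj_r_squared, 0.98)
  expect_lt(f_ex$adj_r_squared, f_pl$adj_r_squared - 0.02)

  expect_error(fit_size_distribution(data.frame(fractional_size = rep(0.1, 5))),
               "at least 10")
})

test_that("bin detector groups runs of nonempty bins and conserves events", {
  set <- bin_avalanches(c(0.5, 1.2, 3.7), delta = 1, t_end = 6)
  av <- set$avalanches
  expect_equal(nrow(av), 2L)
  expect_equal(av$n_bins, c(2L, 1L))
  expect_equal(av$duration, c(2, 1))
  expect_equal(av$size, c(2, 1))
  expect_equal(av$truncated, c(TRUE, FALSE)) # touches the record start
  expect_equal(set$shapes[[1]], c(1L, 1L))
  expect_equal(sum(av$size), set$n_events) # conservation

  # all bins nonempty: a single truncated avalanche spanning the record
  one <- bin_avalanches(seq(0.1, 9.9, by = 0.25), delta = 1, t_end = 10)
  expect_identical(nrow(one$avalanches), 1L)
  expect_true(one$avalanches$truncated)

  # empty input
  empty <- bin_avalanches(numeric(0), delta = 1)
  expect_identical(nrow(empty$avalanches), 0L)

  # widening bins can only merge avalanches, never split them
  set.seed(5)
  ev <- sort(runif(400, 0, 100))
  n_by_delta <- vapply(c(0.1, 0.3, 1, 3), function(d) {
    nrow(bin_avalanches(ev, d, t_end = 100)$avalanches)
  }, numeric(1))
  expect_true(all(diff(n_by_delta) <= 0))
})

test_that("size-duration scaling is exact on scale-free groups", {
  # constant profile: S = c * T^gamma exactly for every duration
  set <- synth_selfsimilar_avalanches(gamma = 1.5, durations = c(4, 8, 16, 32),
                                      counts = 12,
                                      scaling_fn = function(u) rep(2, length(u)),
                                      noise = "none")
  sc <- suppressWarnings(size_duration_scaling(set, min_count = 10))
  expect_equal(sc$gamma, 1.5, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)

  # Poisson noise: recovery within 0.05 at 10^4 avalanches
  setp <- synth_selfsimilar_avalanches(gamma = 1.5,
                                       durations = c(5, 10, 20, 40, 80),
                                       counts = 2000, noise = "poisson",
                                       seed = 17)
  scp <- size_duration_scaling(setp, min_count = 10)
  expect_lt(abs(scp$gamma - 1.5), 0.05)

  expect_error(size_duration_scaling(
    synth_selfsimilar_avalanches(1.5, c(4, 8), 20, noise = "none"),
    min_count = 10), "3 duration groups")
  expect_error(synth_selfsimilar_avalanches(0.9, c(4, 8), 5), "gamma")
})

test_that("shape collapse is exact for self-similar shapes and degrades off-exponent", {
  tent <- function(u) 1 - abs(2 * u - 1)
  # odd bin counts put a knot exactly at u = 0.5, where the tent kinks,
  # so the piecewise-linear interpolants coincide exactly across durations
  set <- synth_selfsimilar_avalanches(gamma = 1.6, durations = c(5, 9, 15, 25),
                                      counts = 12, scaling_fn = tent,
                                      noise = "none")
  col <- shape_collapse(set, 1.6, min_count = 10)
  expect_lt(col$collapse_error, 1e-12)
  expect_equal(range(col$grid), c(0, 1))
  # endpoints pinned to zero
  expect_equal(col$curves[1, ], rep(0, 4))
  expect_equal(col$curves[101, ], rep(0, 4))

  for (dg in c(-0.5, 0.5)) {
    expect_gt(shape_collapse(set, 1.6 + dg, min_count = 10)$collapse_error,
              col$collapse_error + 1e-4)
  }

  # symmetric scaling function: mean shapes symmetric about u = 1/2
  setp <- synth_selfsimilar_avalanches(gamma = 1.5, durations = c(7, 11),
                                       counts = 400, noise = "poisson",
                                       seed = 23)
  for (j in 1:2) {
    sel <- which(setp$avalanches$duration == setp$avalanches$duration[
      cumsum(c(1, 400))[j]])
    ms <- Reduce(`+`, setp$shapes[sel]) / length(sel)
    expect_lt(max(abs(ms - rev(ms))), 4 * sqrt(max(ms) / 400) * 3)
  }

  expect_error(shape_collapse(set, 1.6, durations = 5), "2 durations")
})

test_that("exponent recovery pipeline works end to end on generated truth", {
  set <- synth_selfsimilar_avalanches(gamma = 1.5,
                                      durations = c(5, 9, 17, 33, 65),
                                      counts = 2000, noise = "poisson",
                                      seed = 29)
  sc <- size_duration_scaling(set, min_count = 10)
  expect_lt(abs(sc$gamma - 1.5), 0.05)
  err_true <- shape_collapse(set, sc$gamma)$collapse_error
  expect_lt(err_true, 0.01)
  expect_gt(shape_collapse(set, sc$gamma + 0.5)$collapse_error, err_true)
  expect_gt(shape_collapse(set, sc$gamma - 0.5)$collapse_error, err_true)
})
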