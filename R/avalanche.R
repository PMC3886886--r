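#' Threshold-based avalanche detection
#'
#' An avalanche is a maximal half-open interval `[start, end)` over which
#' the total active fraction is `>= theta` (ties at the threshold belong to
#' the avalanche; the activity series is right-continuous). Its
#' `activation_count` is the number of `+1` events with event time in
#' `[start, end)` and its fractional size is `activation_count / N` with
#' `N` the current total population, so a fractional size of 1 means `N`
#' activations. An avalanche still open at the end of the record is closed
#' at `t_end` and flagged `truncated`.
#'
#' @param traj an [simulate_lmn()] trajectory.
#' @param theta threshold fraction in `(0, 1]`; for an epidemic population
#'   of 100 individuals, `theta = 0.01` means "at least 1 in 100 infected".
#' @return an object of class `lmn_avalanches`: a data frame with columns
#'   `start, end, duration, activation_count, fractional_size, truncated`,
#'   and attributes `theta`, `span`, `rate` (avalanches per time unit) and
#'   `total_activations`.
#' @export
detect_threshold_avalanches <- function(traj, theta) {
  stopifnot(inherits(traj, "lmn_trajectory"))
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 1) {
    stop("'theta' must lie in (0, 1]")
  }
  N <- sum(traj$sizes)
  n_ev <- length(traj$time)
  tot <- c(sum(traj$init), sum(traj$init) + cumsum(traj$direction))
  seg_start <- c(0, traj$time) # segment i is [seg_start[i], seg_start[i+1])
  above <- tot / N >= theta

  runs <- rle(above)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1
  av <- which(runs$values)
  start <- seg_start[starts_idx[av]]
  end_i <- ends_idx[av]
  truncated <- end_i == length(above)
  end <- ifelse(truncated, traj$t_end, seg_start[end_i + 1])

  is_act <- traj$direction == 1L
  act_times <- traj$time[is_act]
  # activations with time in [start, end): #\{t < end\} - #\{t < start\}
  n_act <- findInterval(end, act_times, left.open = TRUE) -
    findInterval(start, act_times, left.open = TRUE)
  keep <- n_act > 0
  out <- data.frame(
    start = start[keep], end = end[keep],
    duration = (end - start)[keep],
    activation_count = n_act[keep],
    fractional_size = n_act[keep] / N,
    truncated = truncated[keep]
  )
  structure(out, class = c("lmn_avalanches", "data.frame"),
            theta = theta, span = traj$t_end,
            rate = nrow(out) / traj$t_end,
            total_activations = sum(is_act))
}

#' Log-log power-law fit of the avalanche size distribution
#'
#' Builds a logarithmically binned empirical density of fractional
#' avalanche sizes and fits an ordinary least-squares line of log10-density
#' on log10-size over the nonempty bins inside `s_range`. The default
#' range's upper bound of 1 reflects that at most `N` activations occur
#' during a scale-free avalanche. Empty bins are dropped, not zero-filled.
#' Truncated avalanches are excluded by default.
#'
#' @param catalog an [detect_threshold_avalanches()] result (or any data
#'   frame with a `fractional_size` column).
#' @param s_range size range `[lo, hi)` used for binning and fitting;
#'   default `[theta, 1)`.
#' @param bins_per_decade log-bin resolution (default 50).
#' @param include_truncated logical.
#' @return an object of class `lmn_powerlaw_fit`: list with `slope`,
#'   `intercept`, `adj_r_squared`, `r_squared`, `n_bins`, `fit_range`,
#'   `edges`, and the binned `table` (`size`, `density`, `count`).
#' @export
fit_size_distribution <- function(catalog, s_range = NULL,
                                  bins_per_decade = 50,
                                  include_truncated = FALSE) {
  s <- catalog$fractional_size
  if (!include_truncated && !is.null(catalog$truncated)) {
    s <- s[!catalog$truncated]
  }
  if (is.null(s_range)) {
    s_range <- c(attr(catalog, "theta") %||% min(s), 1)
  }
  s <- s[s >= s_range[1] & s < s_range[2]]
  if (length(s) < 10) stop("need at least 10 avalanches in range to fit")
  lo <- log10(s_range[1]); hi <- log10(s_range[2])
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  if (edges[length(edges)] < s_range[2]) edges <- c(edges, s_range[2])
  cnt <- graphics::hist(s, breaks = edges, plot = FALSE, right = FALSE)$counts
  width <- diff(edges)
  mid <- sqrt(edges[-length(edges)] * edges[-1])
  nz <- cnt > 0
  m <- sum(nz)
  if (m < 3) stop("fewer than 3 nonempty log-bins; cannot fit")
  dens <- cnt[nz] / (length(s) * width[nz])
  fit <- stats::lm(log10(dens) ~ log10(mid[nz]))
  r2 <- summary(fit)$r.squared
  adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         adj_r_squared = adj, r_squared = r2, n_bins = m,
         fit_range = s_range, edges = edges,
         table = data.frame(size = mid[nz], density = dens, count = cnt[nz])),
    class = "lmn_powerlaw_fit"
  )
}

#' @export
print.lmn_powerlaw_fit <- function(x, ...) {
  cat("<lmn_powerlaw_fit> slope =", signif(x$slope, 5),
      " adj R^2 =", signif(x$adj_r_squared, 5),
      " over", x$n_bins, "bins\n")
  invisible(x)
}

#' Goodness of the power-law fit across network sizes
#'
#' Simulates the model at each network size (seeded), detects threshold
#' avalanches, fits the size distribution and records the adjusted R
#' squared; optionally smooths the curve with a degree-4 least-squares
#' polynomial (skipped for fewer than 6 sizes).
#'
#' @param model a [coarse_lmn()].
#' @param omegas network sizes.
#' @param t_end simulation horizon per size.
#' @param seed base seed; size `i` uses `seed + i`.
#' @param theta avalanche threshold.
#' @param burn_in portion of the record discarded before detection
#'   (default 0).
#' @param ... passed to [fit_size_distribution()].
#' @return data frame `omega, rsq, rsq_smooth, n_avalanches`.
#' @export
rsq_vs_omega <- function(model, omegas, t_end, seed, theta = 0.01,
                         burn_in = 0, ...) {
  stopifnot(inherits(model, "coarse_lmn"))
  rsq <- nav <- rep(NA_real_, length(omegas))
  for (i in seq_along(omegas)) {
    m <- resize(model, omegas[i])
    traj <- simulate_lmn(m, t_end, seed = seed + i)
    if (burn_in > 0) {
      keep <- traj$time > burn_in
      # re-anchor the record at burn_in
      n0 <- traj$init
      for (k in seq_along(traj$sizes)) {
        n0[k] <- traj$init[k] + sum(traj$direction[!keep & traj$block == k])
      }
      traj$time <- traj$time[keep] - burn_in
      traj$block <- traj$block[keep]
      traj$direction <- traj$direction[keep]
      traj$init <- n0
      traj$t_end <- traj$t_end - burn_in
    }
    cat_i <- detect_threshold_avalanches(traj, theta)
    nav[i] <- nrow(cat_i)
    rsq[i] <- tryCatch(fit_size_distribution(cat_i, ...)$adj_r_squared,
                       error = function(e) NA_real_)
  }
  out <- data.frame(omega = omegas, rsq = rsq, rsq_smooth = NA_real_,
                    n_avalanches = nav)
  ok <- is.finite(rsq)
  if (sum(ok) >= 6) {
    pf <- stats::lm(rsq ~ stats::poly(omega, 4, raw = TRUE), data = out[ok, ])
    out$rsq_smooth[ok] <- stats::predict(pf)
  }
  out
}

#' Bin-based avalanche detection
#'
#' Partitions time into half-open bins `[j delta, (j+1) delta)` and defines
#' an avalanche as a maximal run of consecutive nonempty bins delimited by
#' empty bins. The avalanche duration is `(number of bins) * delta`, its
#' size the total number of activation events it contains, and its shape
#' the per-bin event counts. Runs touching the record boundaries are
#' flagged `truncated` (excluded from downstream statistics by default).
#'
#' @param times activation-event times (e.g. `traj$time[traj$direction == 1]`).
#' @param delta bin width (`> 0`), in the record's time unit.
#' @param t_end record end (default: end of the last nonempty bin, in which
#'   case the final run is conservatively flagged truncated).
#' @return an object of class `lmn_binned_avalanches`: list with a data
#'   frame `avalanches` (`start_bin, n_bins, duration, size, truncated`),
#'   the list `shapes` of per-bin counts, `delta`, and `n_events`.
#' @export
bin_avalanches <- function(times, delta, t_end = NULL) {
  if (!is.numeric(delta) || delta <= 0) stop("'delta' must be > 0")
  times <- as.numeric(times)
  if (length(times) == 0) {
    return(structure(list(avalanches = data.frame(start_bin = integer(0),
                                                  n_bins = integer(0),
                                                  duration = numeric(0),
                                                  size = numeric(0),
                                                  truncated = logical(0)),
                          shapes = list(), delta = delta, n_events = 0L),
                     class = "lmn_binned_avalanches"))
  }
  if (any(times < 0)) stop("event times must be >= 0")
  bin <- floor(times / delta)
  tab <- table(bin)
  bins <- as.numeric(names(tab))
  counts <- as.integer(tab)
  last_bin <- if (is.null(t_end)) max(bins) else ceiling(t_end / delta) - 1
  # group maximal runs of consecutive bin indices
  brk <- c(0, which(diff(bins) > 1), length(bins))
  n_av <- length(brk) - 1
  shapes <- vector("list", n_av)
  start_bin <- n_bins <- integer(n_av)
  size <- numeric(n_av)
  truncated <- logical(n_av)
  for (j in seq_len(n_av)) {
    sel <- (brk[j] + 1):brk[j + 1]
    shapes[[j]] <- counts[sel]
    start_bin[j] <- bins[sel[1]]
    n_bins[j] <- length(sel)
    size[j] <- sum(counts[sel])
    truncated[j] <- bins[sel[1]] == 0 || bins[sel[length(sel)]] >= last_bin
  }
  structure(
    list(avalanches = data.frame(start_bin = start_bin, n_bins = n_bins,
                                 duration = n_bins * delta, size = size,
                                 truncated = truncated),
         shapes = shapes, delta = delta, n_events = length(times)),
    class = "lmn_binned_avalanches"
  )
}

#' @export
print.lmn_binned_avalanches <- function(x, ...) {
  cat("<lmn_binned_avalanches>", nrow(x$avalanches), "avalanches from",
      x$n_events, "events (bin width", format(x$delta), ")\n")
  invisible(x)
}

#' Size-duration scaling exponent
#'
#' Organizes avalanches into groups of equal duration and regresses
#' `log <S>(T)` on `log T` by ordinary least squares over groups with at
#' least `min_count` members; the slope is the scaling exponent `gamma`
#' (`<S>(T) ~ T^gamma`, with `2` the critical-branching value and values
#' near `1.3-1.5` reported for cortical avalanche data).
#'
#' @param set an [bin_avalanches()] result.
#' @param min_count minimum group size (default 10).
#' @param t_range optional duration window `[lo, hi]` (same time unit as the
#'   record) restricting the regression to the scaling regime; by default
#'   all populated groups enter. Long records of near-critical models also
#'   contain very long supra-scaling excursions (mean size linear in
#'   duration), which would bias the exponent if included.
#' @param include_truncated logical.
#' @return list with `gamma`, `intercept`, `r_squared` and the group
#'   `table` (`duration, mean_size, count`).
#' @export
size_duration_scaling <- function(set, min_count = 10, t_range = NULL,
                                  include_truncated = FALSE) {
  stopifnot(inherits(set, "lmn_binned_avalanches"))
  av <- set$avalanches
  if (!include_truncated) av <- av[!av$truncated, , drop = FALSE]
  if (!is.null(t_range)) {
    av <- av[av$duration >= t_range[1] & av$duration <= t_range[2], ,
             drop = FALSE]
  }
  if (nrow(av) == 0) stop("no (non-truncated) avalanches")
  grp <- stats::aggregate(size ~ duration, data = av, FUN = mean)
  cnt <- stats::aggregate(size ~ duration, data = av, FUN = length)
  grp$count <- cnt$size
  grp <- grp[grp$count >= min_count, , drop = FALSE]
  if (nrow(grp) < 3) stop("need at least 3 duration groups with >= ",
                          min_count, " avalanches")
  fit <- stats::lm(log(size) ~ log(duration), data = grp)
  list(gamma = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       table = data.frame(duration = grp$duration, mean_size = grp$size,
                          count = grp$count))
}

#' Avalanche shape collapse
#'
#' Within each duration group the mean shape (average events per bin) is
#' multiplied by `T^(1 - gamma)` and its time axis rescaled to `[0, 1]`;
#' since no events occur right before or after an avalanche, the rescaled
#' shapes are pinned to zero at both endpoints. Each curve is linearly
#' interpolated onto a common grid and the collapse error is the mean
#' across-duration variance over the grid, normalized by the squared span
#' of the average rescaled profile (so the error is invariant to the
#' overall scale of the curves): near zero exactly when the shapes are
#' self-similar with exponent `gamma` (the scaling form
#' `s(t, T) = T^(gamma - 1) F(t / T)` for a duration-independent `F`), and
#' strictly larger when the wrong exponent is used.
#'
#' @param set an [bin_avalanches()] result.
#' @param gamma scaling exponent, typically from [size_duration_scaling()].
#' @param durations optional subset of durations (time units) to collapse;
#'   default: all groups with at least `min_count` members.
#' @param min_count minimum group size.
#' @param grid_n number of points of the common rescaled-time grid.
#' @param include_truncated logical.
#' @return an object of class `lmn_collapse`: list with `gamma`,
#'   `durations`, `grid`, `curves` (grid x durations matrix of rescaled
#'   shapes) and `collapse_error`.
#' @export
shape_collapse <- function(set, gamma, durations = NULL, min_count = 10,
                           grid_n = 101, include_truncated = FALSE) {
  stopifnot(inherits(set, "lmn_binned_avalanches"))
  av <- set$avalanches
  keep <- if (include_truncated) rep(TRUE, nrow(av)) else !av$truncated
  if (is.null(durations)) {
    tab <- table(av$duration[keep])
    durations <- as.numeric(names(tab))[tab >= min_count]
  }
  durations <- sort(durations)
  if (length(durations) < 2) stop("need shapes for at least 2 durations")
  grid <- seq(0, 1, length.out = grid_n)
  curves <- matrix(NA_real_, grid_n, length(durations))
  for (j in seq_along(durations)) {
    sel <- which(keep & av$duration == durations[j])
    if (length(sel) == 0) stop("no avalanches of duration ", durations[j])
    nb <- av$n_bins[sel[1]]
    mean_shape <- Reduce(`+`, set$shapes[sel]) / length(sel)
    scaled <- mean_shape * durations[j]^(1 - gamma)
    u <- c(0, (seq_len(nb) - 0.5) / nb, 1)
    v <- c(0, scaled, 0)
    curves[, j] <- stats::approx(u, v, xout = grid)$y
  }
  mean_curve <- rowMeans(curves)
  span <- diff(range(mean_curve))
  if (span == 0) span <- 1 # degenerate all-flat shapes
  err <- mean(apply(curves, 1, stats::var)) / span^2
  structure(list(gamma = gamma, durations = durations, grid = grid,
                 curves = curves, collapse_error = err),
            class = "lmn_collapse")
}

#' @export
print.lmn_collapse <- function(x, ...) {
  cat("<lmn_collapse> gamma =", signif(x$gamma, 5), "over",
      length(x$durations), "durations; collapse error =",
      signif(x$collapse_error, 4), "\n")
  invisible(x)
}

#' Generate self-similar avalanche fixtures
#'
#' Synthetic binned avalanches obeying the scaling form
#' `s(t, T) = T_b^(gamma - 1) F(u)` at bin midpoints `u = (t - 0.5) / T_b`
#' (with `T_b` the duration in bins), optionally with independent Poisson
#' counts around those means. Used to validate exponent recovery and shape
#' collapse against a generator of known truth.
#'
#' @param gamma scaling exponent (`> 1`).
#' @param durations avalanche durations in bins (each `>= 2`).
#' @param counts number of avalanches per duration (recycled).
#' @param scaling_fn the profile `F` on `[0, 1]` (default the inverted
#'   parabola `4 u (1 - u)`).
#' @param noise `"none"` for deterministic means, `"poisson"` for Poisson
#'   counts.
#' @param seed integer seed (used for Poisson noise).
#' @param delta nominal bin width carried in the output.
#' @return an `lmn_binned_avalanches` set (no truncation).
#' @export
synth_selfsimilar_avalanches <- function(gamma, durations, counts,
                                         scaling_fn = function(u) 4 * u * (1 - u),
                                         noise = c("none", "poisson"),
                                         seed = 1, delta = 1) {
  if (!is.numeric(gamma) || gamma <= 1) stop("'gamma' must be > 1")
  durations <- as.integer(durations)
  if (any(durations < 2)) stop("durations must be at least 2 bins")
  noise <- match.arg(noise)
  counts <- rep_len(as.integer(counts), length(durations))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shapes <- list()
  start_bin <- n_bins <- integer(0)
  size <- numeric(0)
  pos <- 1L
  for (j in seq_along(durations)) {
    Tb <- durations[j]
    mean_shape <- Tb^(gamma - 1) * scaling_fn((seq_len(Tb) - 0.5) / Tb)
    for (i in seq_len(counts[j])) {
      s <- if (noise == "poisson") stats::rpois(Tb, mean_shape) else mean_shape
      shapes[[length(shapes) + 1]] <- s
      start_bin <- c(start_bin, pos)
      n_bins <- c(n_bins, Tb)
      size <- c(size, sum(s))
      pos <- pos + Tb + 1L
    }
  }
  ok <- size > 0
  structure(
    list(avalanches = data.frame(start_bin = start_bin[ok],
                                 n_bins = n_bins[ok],
                                 duration = n_bins[ok] * delta,
                                 size = size[ok],
                                 truncated = FALSE),
         shapes = shapes[ok], delta = delta, n_events = sum(size)),
    class = "lmn_binned_avalanches"
  )
}
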