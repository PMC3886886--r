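#' Exact stochastic simulation of the coarse model
#'
#' Direct-method Gillespie simulation of the fractional activity process:
#' exponential waiting times at the total rate `sum(beta_k + delta_k)` and
#' categorical channel choice proportional to the rates, updating one count
#' by one per event. Simulation is seeded through R's RNG (Mersenne
#' Twister) and runs are bit-for-bit reproducible from
#' `(model, seed, t_end)`; the seed is recorded in the trajectory. Models
#' whose gain functions are among the built-ins run in a compiled kernel;
#' user-registered gains fall back to an interpreted loop.
#'
#' @param model a [coarse_lmn()].
#' @param t_end simulation horizon (`> 0`), in the model's time unit.
#' @param seed integer seed.
#' @param init initial count vector (default: the all-inactive origin).
#' @param max_events guard cap on the event count.
#' @return an object of class `lmn_trajectory`: list with `time`, `block`,
#'   `direction` (+1 activation / -1 deactivation), `init`, `final`,
#'   `t_end`, `seed`, `absorbing`, `sizes`, `time_unit`.
#' @export
simulate_lmn <- function(model, t_end, seed, init = NULL, max_events = 5e7) {
  stopifnot(inherits(model, "coarse_lmn"), t_end > 0)
  if (is.null(init)) init <- rep(0L, model$n_blocks)
  init <- as.integer(.check_counts(model, init))
  seed <- as.integer(seed)
  codes_on <- vapply(model$gain_on, .gain_code, integer(1))
  codes_off <- vapply(model$gain_off, .gain_code, integer(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- if (all(codes_on >= 0L) && all(codes_off >= 0L)) {
    .ssa_direct_cpp(model$sizes, model$leak_on, model$leak_off,
                    codes_on, codes_off, model$block_weights,
                    model$block_input, init, t_end, max_events)
  } else {
    .ssa_direct_r(model, init, t_end, max_events)
  }
  structure(
    list(time = res$time, block = res$block, direction = res$direction,
         init = init, final = res$final, t_end = t_end, seed = seed,
         absorbing = isTRUE(res$absorbing), sizes = model$sizes,
         time_unit = model$time_unit),
    class = "lmn_trajectory"
  )
}

# interpreted fallback for user-registered gain functions; draws from the
# RNG exactly like the compiled kernel, so the two paths produce identical
# event logs for the same (model, seed, t_end)
.ssa_direct_r <- function(model, init, t_end, max_events) {
  n <- init
  t <- 0
  ev_t <- numeric(0); ev_k <- integer(0); ev_d <- integer(0)
  absorbing <- FALSE
  repeat {
    pr <- coarse_propensities(model, n)
    rates <- c(rbind(pr$birth, pr$death)) # b1, d1, b2, d2, ...
    total <- sum(rates)
    if (total <= 0) { absorbing <- TRUE; break }
    t <- t + stats::rexp(1) / total
    if (t > t_end) break
    r <- stats::runif(1) * total
    cum <- cumsum(rates)
    ch <- which(r < cum)[1]
    if (is.na(ch)) ch <- length(rates)
    k <- (ch + 1L) %/% 2L
    dir <- if (ch %% 2L == 1L) 1L else -1L
    n[k] <- n[k] + dir
    ev_t <- c(ev_t, t); ev_k <- c(ev_k, k); ev_d <- c(ev_d, dir)
    if (length(ev_t) > max_events) stop("event count exceeded 'max_events'")
  }
  list(time = ev_t, block = ev_k, direction = ev_d,
       absorbing = absorbing, final = n)
}

#' @export
print.lmn_trajectory <- function(x, ...) {
  cat("<lmn_trajectory>", length(x$time), "events over",
      format(x$t_end), x$time_unit, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Reconstruct activity series from an event trajectory
#'
#' The piecewise-constant, right-continuous per-block fraction series
#' `z_k(t)` and the total-activity series `sum_k n_k(t) / N`.
#'
#' @param traj an [simulate_lmn()] trajectory.
#' @param times optional query times (default: the native event times,
#'   prefixed with time 0).
#' @return data frame with columns `time`, `z1..zM`, `total`.
#' @export
trajectory_to_series <- function(traj, times = NULL) {
  stopifnot(inherits(traj, "lmn_trajectory"))
  M <- length(traj$sizes)
  n_ev <- length(traj$time)
  # counts right after each event
  counts <- matrix(rep(traj$init, each = n_ev + 1), n_ev + 1, M)
  if (n_ev > 0) {
    for (k in seq_len(M)) {
      sel <- traj$block == k
      counts[-1, k] <- traj$init[k] + cumsum(ifelse(sel, traj$direction, 0L))
    }
  }
  ev_times <- c(0, traj$time)
  if (is.null(times)) {
    idx <- seq_len(n_ev + 1)
    times_out <- ev_times
  } else {
    times <- as.numeric(times)
    if (any(times < 0)) stop("query times must be >= 0")
    idx <- findInterval(times, ev_times) # right-continuous step lookup
    times_out <- times
  }
  z <- sweep(counts[idx, , drop = FALSE], 2, traj$sizes, "/")
  colnames(z) <- paste0("z", seq_len(M))
  out <- data.frame(time = times_out)
  out <- cbind(out, z)
  out$total <- rowSums(counts[idx, , drop = FALSE]) / sum(traj$sizes)
  out
}

#' Time-weighted empirical stationary distribution
#'
#' Occupancy of lattice states weighted by the time spent in each (not by
#' event counts), over `(burn_in, t_end]`.
#'
#' @param traj an [simulate_lmn()] trajectory.
#' @param burn_in initial time span to discard (`< t_end`).
#' @return an `lmn_distribution`.
#' @export
empirical_stationary <- function(traj, burn_in = 0) {
  stopifnot(inherits(traj, "lmn_trajectory"))
  if (burn_in >= traj$t_end) stop("'burn_in' must be smaller than t_end")
  space <- lattice_state_space(traj$sizes)
  M <- length(traj$sizes)
  n_ev <- length(traj$time)
  counts <- matrix(rep(traj$init, each = n_ev + 1), n_ev + 1, M)
  if (n_ev > 0) {
    for (k in seq_len(M)) {
      sel <- traj$block == k
      counts[-1, k] <- traj$init[k] + cumsum(ifelse(sel, traj$direction, 0L))
    }
  }
  seg_start <- pmax(c(0, traj$time), burn_in)
  seg_end <- pmin(c(traj$time, traj$t_end), traj$t_end)
  w <- pmax(seg_end - seg_start, 0)
  idx <- state_to_index(space, counts)
  mass <- numeric(space$n_states)
  agg <- rowsum(w, idx)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  .new_distribution(mass / sum(mass), space, time = "empirical")
}

# ---- event-log import/export ----------------------------------------------

#' Write or read an event log
#'
#' TSV with columns `time, block, direction` plus a JSON header sidecar
#' (`<path>.json`) recording sizes, seed, horizon, initial state and time
#' unit. Readers validate strictly increasing times.
#'
#' @param traj an [simulate_lmn()] trajectory.
#' @param path TSV file path.
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   an `lmn_trajectory`.
#' @export
write_event_log <- function(traj, path) {
  stopifnot(inherits(traj, "lmn_trajectory"))
  df <- data.frame(time = traj$time, block = traj$block,
                   direction = traj$direction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hdr <- list(sizes = traj$sizes, init = traj$init, t_end = traj$t_end,
              seed = traj$seed, absorbing = traj$absorbing,
              time_unit = traj$time_unit)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.delim(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.unsorted(df$time, strictly = TRUE)) {
    stop("event log times must be strictly increasing")
  }
  init <- as.integer(hdr$init)
  final <- init
  if (nrow(df) > 0) {
    for (k in seq_along(hdr$sizes)) {
      final[k] <- init[k] + sum(df$direction[df$block == k])
    }
  }
  structure(
    list(time = df$time, block = as.integer(df$block),
         direction = as.integer(df$direction),
         init = init, final = final, t_end = hdr$t_end,
         seed = hdr$seed, absorbing = isTRUE(hdr$absorbing),
         sizes = as.integer(hdr$sizes), time_unit = hdr$time_unit),
    class = "lmn_trajectory"
  )
}
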