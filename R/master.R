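#' Build the master-equation generator on the count lattice
#'
#' Constructs the sparse rate matrix `Q` of the fractional activity process:
#' `Q[i, j]` is the rate of the single-step move `n -> n + e_k` (birth) or
#' `n -> n - e_k` (death) between the lattice states with indices `i`, `j`,
#' and the diagonal is minus the row sum, so every row of `Q` sums to zero.
#' The master equation reads `dp/dt = p Q` for the row vector `p`.
#'
#' @param model a [coarse_lmn()].
#' @param cap maximum number of lattice states (guards against accidental
#'   state-space explosions; resize the model if exceeded).
#' @return an object of class `lmn_generator`: list with the sparse matrix
#'   `Q`, the [lattice_state_space()] `space`, and the `model`.
#' @export
build_generator <- function(model, cap = 5e5) {
  stopifnot(inherits(model, "coarse_lmn"))
  card <- prod(model$sizes + 1)
  if (card > cap) {
    stop("lattice has ", card, " states, above the cap of ", cap,
         "; resize() the model or raise 'cap'")
  }
  space <- lattice_state_space(model$sizes)
  states <- space$states
  M <- model$n_blocks
  z <- sweep(states, 2, model$sizes, "/")
  U <- sweep(z %*% t(model$block_weights), 2, model$block_input, "+")
  radix <- cumprod(c(1, utils::head(model$sizes + 1, -1)))

  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (k in seq_len(M)) {
    phi <- gain_function(model$gain_on[k])(U[, k])
    psi <- gain_function(model$gain_off[k])(U[, k])
    birth <- (model$sizes[k] - states[, k]) * (model$leak_on[k] + phi)
    death <- states[, k] * (model$leak_off[k] + psi)
    if (any(birth < 0) || any(death < 0)) {
      stop("negative propensity in block ", k,
           "; check that the gain functions are nonnegative on the model's inputs")
    }
    up <- which(states[, k] < model$sizes[k] & birth > 0)
    dn <- which(states[, k] > 0 & death > 0)
    ii <- c(ii, up, dn)
    jj <- c(jj, up + radix[k], dn - radix[k])
    xx <- c(xx, birth[up], death[dn])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(space$n_states, space$n_states))
  Matrix::diag(Q) <- -Matrix::rowSums(Q)
  structure(list(Q = Q, space = space, model = model),
            class = "lmn_generator")
}

#' @export
print.lmn_generator <- function(x, ...) {
  cat("<lmn_generator>", x$space$n_states, "states,",
      length(x$Q@x), "stored entries\n")
  invisible(x)
}

#' Check irreducibility of a generator
#'
#' A leaky model (all leak rates positive) induces an irreducible chain;
#' this verifies strong connectivity of the transition graph.
#'
#' @param gen an [build_generator()] result.
#' @return logical.
#' @export
is_irreducible <- function(gen) {
  Q <- gen$Q
  Matrix::diag(Q) <- 0
  g <- igraph::graph_from_adjacency_matrix(Matrix::drop0(Q) != 0, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

.new_distribution <- function(p, space, time = "stationary", omega = NA_real_) {
  structure(list(p = as.numeric(p), space = space, time = time, omega = omega),
            class = "lmn_distribution")
}

#' @export
print.lmn_distribution <- function(x, ...) {
  cat("<lmn_distribution>", x$space$n_states, "states, time:",
      if (identical(x$time, "stationary")) "stationary" else format(x$time),
      "\n")
  invisible(x)
}

#' Stationary distribution of the lattice chain
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`. For lattices up to `gth_cap` states
#' the Grassmann-Taksar-Heyman state-reduction algorithm is used: it
#' involves no subtractions, so every component of `pi` -- including
#' deep-tail probabilities such as `exp(-80)` relative to the mode, which
#' matter for potential-landscape tails -- is computed with full relative
#' accuracy. Larger systems are solved by replacing one balance equation of
#' the sparse system with the normalization row (LU), with uniformized
#' power iteration as a fallback; in that regime probabilities below about
#' `1e-16` of the mode are at the solver's noise floor. For a leaky
#' (irreducible) model `pi` is strictly positive.
#'
#' @param gen an [build_generator()] result.
#' @param tol residual tolerance relative to `max(abs(Q))`.
#' @param method `"auto"` (GTH up to `gth_cap` states, else sparse LU),
#'   `"gth"`, or `"sparse"`.
#' @param gth_cap largest state count handled by the dense GTH routine.
#' @return an `lmn_distribution`.
#' @export
solve_stationary <- function(gen, tol = 1e-10,
                             method = c("auto", "gth", "sparse"),
                             gth_cap = 4096) {
  stopifnot(inherits(gen, "lmn_generator"))
  method <- match.arg(method)
  Q <- gen$Q
  n <- nrow(Q)
  if (method == "gth" || (method == "auto" && n <= gth_cap)) {
    p <- .gth_stationary_cpp(as.matrix(Q))
  } else {
    A <- Matrix::t(Q)
    A[n, ] <- 1
    b <- c(rep(0, n - 1), 1)
    p <- tryCatch(as.numeric(Matrix::solve(A, b)),
                  error = function(e) NULL)
    if (is.null(p) || anyNA(p) || min(p) < -1e-8) {
      p <- .stationary_power(Q)
    }
    p[p < 0] <- 0
    p <- p / sum(p)
  }
  res <- max(abs(as.numeric(p %*% Q)))
  if (res > tol * max(abs(Q@x))) {
    stop("stationary solve failed (residual ", format(res), "); ",
         "the chain may be reducible - leaky models (positive leak rates) ",
         "guarantee irreducibility")
  }
  om <- if (!is.null(gen$model)) network_size(gen$model) else NA_real_
  .new_distribution(p, gen$space, time = "stationary", omega = om)
}

# uniformized power iteration fallback for very large lattices
.stationary_power <- function(Q, max_iter = 200000L, tol = 1e-13) {
  n <- nrow(Q)
  lambda <- max(-Matrix::diag(Q)) * 1.05
  P <- Q / lambda + Matrix::Diagonal(n)
  p <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    p2 <- as.numeric(p %*% P)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}

#' Transient master-equation solve by uniformization
#'
#' Integrates `dp/dt = p Q` from `p0` to each requested time using the
#' uniformization (randomization) series
#' `p(t) = sum_k Pois(k; Lambda t) p0 P^k` with
#' `P = I + Q / Lambda`, which conserves probability mass to machine
#' precision and is robust for stiff generators. Negatives below `-1e-12`
#' abort; smaller ones are clipped and the vector renormalized.
#'
#' @param gen an [build_generator()] result.
#' @param p0 initial `lmn_distribution`, or a count vector for a point mass.
#' @param times increasing nonnegative times.
#' @param tol truncation tolerance of the Poisson series.
#' @return list of `lmn_distribution`, one per time.
#' @export
solve_transient <- function(gen, p0, times, tol = 1e-12) {
  stopifnot(inherits(gen, "lmn_generator"))
  if (!inherits(p0, "lmn_distribution")) {
    p <- numeric(gen$space$n_states)
    p[state_to_index(gen$space, p0)] <- 1
    p0 <- .new_distribution(p, gen$space, time = 0)
  }
  times <- as.numeric(times)
  if (is.unsorted(times) || any(times < 0)) stop("'times' must be increasing and >= 0")
  n <- nrow(gen$Q)
  lambda <- max(max(-Matrix::diag(gen$Q)), 1e-300) * 1.02
  P <- gen$Q / lambda + Matrix::Diagonal(n)
  om <- if (!is.null(gen$model)) network_size(gen$model) else NA_real_

  out <- vector("list", length(times))
  p <- p0$p
  t_prev <- 0
  for (s in seq_along(times)) {
    dt <- times[s] - t_prev
    # split very stiff steps to bound the series length per step
    n_sub <- max(1L, ceiling(lambda * dt / 5e4))
    for (sub in seq_len(n_sub)) {
      m <- lambda * dt / n_sub
      if (m == 0) break
      kmax <- as.integer(stats::qpois(tol, m, lower.tail = FALSE)) + 10L
      w <- stats::dpois(0:kmax, m)
      acc <- w[1] * p
      v <- p
      for (k in seq_len(kmax)) {
        v <- as.numeric(v %*% P)
        if (w[k + 1] > 0) acc <- acc + w[k + 1] * v
      }
      p <- acc / sum(acc)
    }
    if (min(p) < -1e-12) stop("transient solve produced negative probabilities")
    p[p < 0] <- 0
    p <- p / sum(p)
    out[[s]] <- .new_distribution(p, gen$space, time = times[s], omega = om)
    t_prev <- times[s]
  }
  out
}

#' Closed-form stationary law of a one-dimensional birth-death chain
#'
#' The detailed-balance product form
#' `pi(n) / pi(0) = prod_{m=1..n} lambda_{m-1} / mu_m`, normalized. This is
#' the independent oracle against which the sparse master-equation solver is
#' validated for every single-block model.
#'
#' @param birth rates `lambda_0 .. lambda_{N-1}` (leaving states `0..N-1`
#'   upward), all `> 0`.
#' @param death rates `mu_1 .. mu_N` (leaving states `1..N` downward),
#'   all `> 0`.
#' @return an `lmn_distribution` over states `0..N`.
#' @export
bd_stationary_closedform <- function(birth, death) {
  birth <- as.numeric(birth); death <- as.numeric(death)
  if (length(birth) != length(death)) stop("'birth' and 'death' must have equal length")
  if (any(birth <= 0) || any(death <= 0)) stop("all rates must be strictly positive")
  lw <- c(0, cumsum(log(birth) - log(death)))
  lw <- lw - max(lw)
  p <- exp(lw) / sum(exp(lw))
  .new_distribution(p, lattice_state_space(length(birth)), time = "stationary")
}

#' Mean first-passage time on the lattice chain
#'
#' Expected time to first hit the target set from `start`, from the exact
#' sparse linear system: `tau = 0` on the target and
#' `sum_j Q[i, j] tau[j] = -1` elsewhere.
#'
#' @param gen an [build_generator()] result.
#' @param start count vector of the starting state.
#' @param target matrix (one row per state) or vector of target counts.
#' @return numeric scalar (0 if `start` is in the target).
#' @export
mean_first_passage <- function(gen, start, target) {
  stopifnot(inherits(gen, "lmn_generator"))
  i0 <- state_to_index(gen$space, start)
  it <- unique(state_to_index(gen$space, target))
  if (length(it) == 0) stop("'target' must be nonempty")
  if (i0 %in% it) return(0)
  keep <- setdiff(seq_len(gen$space$n_states), it)
  A <- gen$Q[keep, keep, drop = FALSE]
  tau <- tryCatch(as.numeric(Matrix::solve(A, rep(-1, length(keep)))),
                  error = function(e) stop("first-passage system is singular; ",
                                           "is the target reachable?"))
  if (anyNA(tau) || any(tau < 0)) stop("first-passage solve failed; is the target reachable?")
  tau[match(i0, keep)]
}

#' Mean exit time from a single state
#'
#' The exponential holding time `1 / (sum_k beta_k + delta_k)` at the given
#' state. For the SISa model at the inactive origin this is `1 / (N a)`,
#' inversely proportional to the network size. Returns `Inf` (with an
#' `absorbing` attribute) when all rates vanish.
#'
#' @param model a [coarse_lmn()].
#' @param counts integer count vector.
#' @return numeric scalar; `Inf` if the state is absorbing.
#' @export
state_exit_time <- function(model, counts) {
  pr <- coarse_propensities(model, counts)
  tot <- sum(pr$birth) + sum(pr$death)
  if (tot == 0) {
    return(structure(Inf, absorbing = TRUE))
  }
  1 / tot
}

#' Maximum absolute affinity of a distribution on the chain
#'
#' For each ordered transition pair `n -> n'` present in the generator, the
#' affinity is `ln[p(n) Q(n, n')] - ln[p(n') Q(n', n)]`; the maximum of its
#' absolute value over all transitions is zero exactly when `p` satisfies
#' detailed balance on `Q` (thermodynamic equilibrium). Any one-dimensional
#' birth-death chain is in detailed balance at stationarity, so a strictly
#' positive value at the stationary law requires at least two blocks (a
#' genuine non-equilibrium steady state). The distribution is supplied
#' explicitly so the quantity can also be tracked along transient solves.
#'
#' @param gen an [build_generator()] result.
#' @param p an `lmn_distribution` (strictly positive on states with
#'   transitions).
#' @return nonnegative scalar.
#' @export
max_abs_affinity <- function(gen, p) {
  stopifnot(inherits(gen, "lmn_generator"), inherits(p, "lmn_distribution"))
  Q <- methods::as(Matrix::drop0(gen$Q), "TsparseMatrix")
  i <- Q@i + 1L; j <- Q@j + 1L; x <- Q@x
  off <- i != j
  i <- i[off]; j <- j[off]; x <- x[off]
  n <- nrow(Q)
  key <- (i - 1) * n + j
  rkey <- (j - 1) * n + i
  rev_pos <- match(rkey, key)
  if (anyNA(rev_pos)) stop("a transition has zero reverse rate; affinity undefined")
  pv <- p$p
  if (any(pv[i] <= 0)) stop("'p' must be strictly positive on states with transitions")
  aff <- log(pv[i] * x) - log(pv[j] * x[rev_pos])
  max(abs(aff))
}

# ---- distribution import/export -------------------------------------------

#' Export or import a lattice distribution as TSV
#'
#' Writes columns `n_1 .. n_M, probability` plus a JSON sidecar
#' (`<path>.json`) recording the network size, time tag and block sizes.
#'
#' @param p an `lmn_distribution`.
#' @param path TSV file path.
#' @return `write_distribution()` returns `path` invisibly;
#'   `read_distribution()` returns an `lmn_distribution`.
#' @export
write_distribution <- function(p, path) {
  stopifnot(inherits(p, "lmn_distribution"))
  df <- as.data.frame(p$space$states)
  df$probability <- p$p
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(sizes = p$space$sizes, time = p$time, omega = p$omega)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  space <- lattice_state_space(side$sizes)
  idx <- state_to_index(space, as.matrix(df[, seq_along(side$sizes), drop = FALSE]))
  p <- numeric(space$n_states)
  p[idx] <- df$probability
  tm <- side$time
  if (is.character(tm) && !identical(tm, "stationary")) tm <- as.numeric(tm)
  .new_distribution(p, space, time = tm, omega = side$omega %||% NA_real_)
}
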