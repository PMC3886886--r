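#' Macroscopic (deterministic) limit of a coarse model
#'
#' The thermodynamic-limit ODE system on the unit hypercube:
#' `dx_k/dt = g_k(x) = (1 - x_k)[a_k + phi_k(ubar_k(x))] -
#' x_k[b_k + psi_k(ubar_k(x))]`. The hypercube is forward-invariant
#' (`g_k >= 0` at `x_k = 0`, `g_k <= 0` at `x_k = 1`).
#'
#' @param model a [coarse_lmn()].
#' @return an object of class `lmn_macro`: list with `drift(x)`,
#'   `percap(x)` (per-capita on/off rates) and the model.
#' @export
macro_system <- function(model) {
  stopifnot(inherits(model, "coarse_lmn"))
  M <- model$n_blocks
  phis <- lapply(model$gain_on, gain_function)
  psis <- lapply(model$gain_off, gain_function)
  percap <- function(x) {
    u <- drop(model$block_input + model$block_weights %*% x)
    on <- off <- numeric(M)
    for (k in seq_len(M)) {
      on[k] <- model$leak_on[k] + phis[[k]](u[k])
      off[k] <- model$leak_off[k] + psis[[k]](u[k])
    }
    list(on = on, off = off)
  }
  drift <- function(x) {
    r <- percap(x)
    (1 - x) * r$on - x * r$off
  }
  structure(list(drift = drift, percap = percap, model = model),
            class = "lmn_macro")
}

#' Integrate the macroscopic equations
#'
#' Adaptive Cash-Karp Runge-Kutta (4/5) integration of the macroscopic ODE;
#' the solution is clipped to the unit hypercube (excursions beyond `1e-9`
#' abort).
#'
#' @param system an [macro_system()] (a [coarse_lmn()] is accepted and
#'   converted).
#' @param x0 initial fractions in `[0, 1]^M`.
#' @param times increasing output times starting at the initial time.
#' @param rtol,atol local error tolerances.
#' @return matrix with one row per time (attribute `times`).
#' @export
integrate_macro <- function(system, x0, times, rtol = 1e-8, atol = 1e-10) {
  if (inherits(system, "coarse_lmn")) system <- macro_system(system)
  stopifnot(inherits(system, "lmn_macro"))
  M <- system$model$n_blocks
  x0 <- as.numeric(x0)
  if (length(x0) != M || any(x0 < 0) || any(x0 > 1)) {
    stop("'x0' must lie in the unit hypercube [0,1]^M")
  }
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("'times' must be increasing")
  out <- matrix(NA_real_, length(times), M)
  x <- x0
  out[1, ] <- x
  t <- times[1]
  for (s in seq_along(times)[-1]) {
    x <- .rk45(system$drift, x, t, times[s], rtol, atol)
    if (any(x < -1e-9) || any(x > 1 + 1e-9)) {
      stop("macroscopic solution left the unit hypercube")
    }
    x <- pmin(pmax(x, 0), 1)
    out[s, ] <- x
    t <- times[s]
  }
  colnames(out) <- system$model$block_names
  attr(out, "times") <- times
  out
}

# Cash-Karp embedded RK45 with step-size control
.rk45 <- function(f, x, t0, t1, rtol, atol) {
  if (t1 <= t0) return(x)
  a <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
  b <- list(
    c(), c(1/5),
    c(3/40, 9/40),
    c(3/10, -9/10, 6/5),
    c(-11/54, 5/2, -70/27, 35/27),
    c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096)
  )
  c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  t <- t0
  h <- (t1 - t0) / 10
  while (t < t1) {
    h <- min(h, t1 - t)
    k <- vector("list", 6)
    k[[1]] <- f(x)
    for (i in 2:6) {
      xi <- x
      for (j in seq_len(i - 1)) xi <- xi + h * b[[i]][j] * k[[j]]
      k[[i]] <- f(xi)
    }
    x5 <- x; x4 <- x
    for (i in 1:6) {
      x5 <- x5 + h * c5[i] * k[[i]]
      x4 <- x4 + h * c4[i] * k[[i]]
    }
    err <- max(abs(x5 - x4) / (atol + rtol * pmax(abs(x), abs(x5))))
    if (is.finite(err) && err <= 1) {
      t <- t + h
      x <- x5
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      h <- h * max(0.1, 0.9 * err^(-0.25))
      if (h < (t1 - t0) * 1e-14) stop("macroscopic integrator step size underflow")
    }
  }
  x
}

#' Macroscopic fixed point
#'
#' Integrates from the hypercube center over a long horizon, then polishes
#' the root of the drift with damped Newton iterations (numerical Jacobian)
#' to `||g(x*)|| <= 1e-12`. A small multistart over hypercube corners warns
#' when several distinct roots are found (the landscape analysis assumes a
#' unique, stable, interior fixed point) or when the fixed point is
#' boundary-adjacent.
#'
#' @param system an [macro_system()] or [coarse_lmn()].
#' @param t_relax integration horizon used to enter the basin (default set
#'   by the slowest leak/deactivation scale).
#' @param multistart logical; probe additional starting points.
#' @return numeric vector `x*`.
#' @export
find_fixed_point <- function(system, t_relax = NULL, multistart = FALSE) {
  if (inherits(system, "coarse_lmn")) system <- macro_system(system)
  stopifnot(inherits(system, "lmn_macro"))
  M <- system$model$n_blocks
  rate_scale <- max(1e-12, min(system$model$leak_off + system$model$leak_on))
  if (is.null(t_relax)) t_relax <- 50 / rate_scale
  starts <- list(rep(0.5, M))
  if (multistart) {
    starts <- c(starts, list(rep(0.05, M), rep(0.95, M)))
  }
  roots <- list()
  for (x0 in starts) {
    x <- integrate_macro(system, x0, c(0, t_relax))[2, ]
    x <- .newton_polish(system$drift, x)
    if (!is.null(x)) roots[[length(roots) + 1]] <- x
  }
  if (length(roots) == 0) stop("no convergence to a macroscopic fixed point")
  xstar <- roots[[1]]
  if (length(roots) > 1) {
    dis <- vapply(roots[-1], function(r) max(abs(r - xstar)), numeric(1))
    if (any(dis > 1e-6)) warning("multiple macroscopic fixed points detected; ",
                                 "returning the one reached from the center")
  }
  if (any(xstar < 1e-3) || any(xstar > 1 - 1e-3)) {
    warning("macroscopic fixed point is boundary-adjacent")
  }
  unname(xstar)
}

.newton_polish <- function(f, x, tol = 1e-12, max_iter = 100L) {
  for (i in seq_len(max_iter)) {
    g <- f(x)
    if (max(abs(g)) <= tol) return(x)
    J <- .num_jacobian(f, x)
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- pmin(pmax(x + lam * step, 0), 1)
      if (max(abs(f(xn))) < max(abs(g)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  if (max(abs(f(x))) <= 1e-10) x else NULL
}

.num_jacobian <- function(f, x, h = 1e-6) {
  M <- length(x)
  J <- matrix(0, M, M)
  for (j in seq_len(M)) {
    e <- numeric(M); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

#' Linear noise approximation at the macroscopic fixed point
#'
#' Gaussian fluctuations of the fractional activity process around the
#' stable fixed point `x*`: the Jacobian `A` of the drift at `x*` (analytic
#' when gain derivatives are registered, else central finite differences),
#' the diffusion matrix `D = diag(r_k / N_k)` with
#' `r_k = (1 - x*_k)(a_k + phi_k) + x*_k(b_k + psi_k)` (the standard
#' system-size expansion for lattice jumps of size `1/N_k`), and the
#' stationary covariance `C` solving the Lyapunov equation
#' `A C + C A' + D = 0`. Per-block standard deviations scale as
#' `N_k^{-1/2}`; for zero-coupling single-block models
#' `C = x*(1 - x*) / N`, the exact binomial variance.
#'
#' @param model a [coarse_lmn()].
#' @param xstar optional precomputed fixed point.
#' @return an object of class `lmn_lna`: list with `xstar`, `A`, `D`, `C`,
#'   `stable`, and `model`.
#' @export
lna <- function(model, xstar = NULL) {
  stopifnot(inherits(model, "coarse_lmn"))
  sys <- macro_system(model)
  if (is.null(xstar)) xstar <- find_fixed_point(sys)
  A <- .macro_jacobian(model, xstar)
  ev <- eigen(A, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  if (!stable) stop("LNA invalid: unstable fixed point")
  r <- sys$percap(xstar)
  rk <- (1 - xstar) * r$on + xstar * r$off
  D <- diag(rk / model$sizes, nrow = model$n_blocks)
  M <- model$n_blocks
  K <- kronecker(diag(M), A) + kronecker(A, diag(M))
  C <- matrix(solve(K, -as.vector(D)), M, M)
  C <- (C + t(C)) / 2
  structure(list(xstar = xstar, A = A, D = D, C = C, stable = stable,
                 model = model),
            class = "lmn_lna")
}

# analytic Jacobian where gain derivatives are registered, finite
# differences otherwise
.macro_jacobian <- function(model, x) {
  M <- model$n_blocks
  dphi <- lapply(model$gain_on, gain_deriv)
  dpsi <- lapply(model$gain_off, gain_deriv)
  if (any(vapply(c(dphi, dpsi), is.null, logical(1)))) {
    return(.num_jacobian(macro_system(model)$drift, x))
  }
  u <- drop(model$block_input + model$block_weights %*% x)
  J <- matrix(0, M, M)
  for (k in seq_len(M)) {
    phi <- gain_function(model$gain_on[k])(u[k])
    psi <- gain_function(model$gain_off[k])(u[k])
    dphik <- dphi[[k]](u[k])
    dpsik <- dpsi[[k]](u[k])
    for (l in seq_len(M)) {
      J[k, l] <- (1 - x[k]) * dphik * model$block_weights[k, l] -
        x[k] * dpsik * model$block_weights[k, l]
    }
    J[k, k] <- J[k, k] - (model$leak_on[k] + phi) - (model$leak_off[k] + psi)
  }
  J
}

#' @export
print.lmn_lna <- function(x, ...) {
  cat("<lmn_lna> x* =", paste(signif(x$xstar, 6), collapse = ", "),
      "; stable:", x$stable, "\n")
  invisible(x)
}

#' Discretize the LNA Gaussian onto the count lattice
#'
#' Evaluates the LNA Gaussian density at the lattice fractions and
#' renormalizes over the lattice. The fraction of Gaussian mass lying
#' outside the unit hypercube (a known pathology of the approximation at
#' small sizes) is attached as attribute `mass_outside` (estimated by the
#' per-dimension marginal bound for `M > 1`, exact for `M = 1`).
#'
#' @param result an [lna()] result.
#' @param space a [lattice_state_space()] matching the model sizes.
#' @return an `lmn_distribution`.
#' @export
lna_lattice_distribution <- function(result, space = lattice_state_space(result$model)) {
  stopifnot(inherits(result, "lmn_lna"))
  C <- result$C
  Ci <- tryCatch(solve(C), error = function(e) stop("singular LNA covariance"))
  z <- sweep(space$states, 2, space$sizes, "/")
  d <- sweep(z, 2, result$xstar, "-")
  q <- rowSums((d %*% Ci) * d)
  logp <- -q / 2
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sd_k <- sqrt(diag(C))
  out_k <- stats::pnorm(-result$xstar / sd_k) +
    stats::pnorm((result$xstar - 1) / sd_k)
  dist <- .new_distribution(p, space, time = "stationary",
                            omega = network_size(result$model))
  attr(dist, "mass_outside") <- 1 - prod(1 - out_k)
  dist
}

#' Quadratic (LNA) potential energy landscape
#'
#' `V(z) = (z - x*)' C^{-1} (z - x*) / 2`, shifted so the lattice minimum is
#' zero: the parabolic surface against which the exact landscape's flat
#' left tail and steep right tail stand out near criticality.
#'
#' @inheritParams lna_lattice_distribution
#' @return an `lmn_landscape`.
#' @export
lna_landscape <- function(result, space = lattice_state_space(result$model)) {
  stopifnot(inherits(result, "lmn_lna"))
  Ci <- tryCatch(solve(result$C), error = function(e) stop("singular LNA covariance"))
  z <- sweep(space$states, 2, space$sizes, "/")
  d <- sweep(z, 2, result$xstar, "-")
  V <- rowSums((d %*% Ci) * d) / 2
  V <- V - min(V)
  ground <- which(V <= 1e-12)
  structure(
    list(V = V, ground_states = ground, ground_index = min(ground),
         space = space, omega = network_size(result$model), source = "lna"),
    class = "lmn_landscape"
  )
}

#' Export an LNA result as JSON
#'
#' @param result an [lna()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lna <- function(result, path) {
  stopifnot(inherits(result, "lmn_lna"))
  jsonlite::write_json(
    list(xstar = result$xstar,
         A = apply(result$A, 1, as.list, simplify = FALSE),
         D = apply(result$D, 1, as.list, simplify = FALSE),
         C = apply(result$C, 1, as.list, simplify = FALSE),
         stable = result$stable),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
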