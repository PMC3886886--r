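#' Potential energy landscape of a lattice distribution
#'
#' `V(n) = ln[p(n*) / p(n)]`, where `n*` is a most probable state, so that
#' `min V = 0` on the ground states and `exp(-V) / Z` reconstructs the
#' source distribution (a Boltzmann-Gibbs form with the temperature absorbed
#' into the potential; all quantities are in nats). States whose probability
#' ties the maximum within relative tolerance `1e-9` are all recorded as
#' ground states; the lexicographically smallest (lowest index) is used as
#' `n*`.
#'
#' @param p an `lmn_distribution`, strictly positive (guaranteed for leaky
#'   models at stationarity).
#' @param strict if `TRUE` (default), zero-probability states are an error;
#'   if `FALSE` they receive `V = Inf` (useful when a large-lattice solver
#'   has underflowed genuinely positive deep-tail probabilities to zero).
#' @return an object of class `lmn_landscape`: list with `V`, `ground_states`
#'   (indices), `ground_index` (the representative `n*`), `space`, `omega`
#'   and `source` tags.
#' @export
potential_from_distribution <- function(p, strict = TRUE) {
  stopifnot(inherits(p, "lmn_distribution"))
  if (strict && any(p$p <= 0)) {
    stop("distribution has zero-probability states; the potential requires ",
         "strictly positive probabilities (use leaky parameters)")
  }
  pmax_ <- max(p$p)
  ground <- which(p$p >= pmax_ * (1 - 1e-9))
  nstar <- min(ground)
  V <- log(p$p[nstar]) - log(p$p) # p = 0 -> V = Inf under strict = FALSE
  V[ground] <- 0
  structure(
    list(V = V, ground_states = ground, ground_index = nstar,
         space = p$space, omega = p$omega, source = p$time),
    class = "lmn_landscape"
  )
}

#' @export
print.lmn_landscape <- function(x, ...) {
  cat("<lmn_landscape>", x$space$n_states, "states; ground state(s) at index",
      paste(x$ground_states, collapse = ", "), "\n")
  invisible(x)
}

#' Thermodynamic summary of a distribution
#'
#' The per-size thermodynamic quantities of the landscape picture, all in
#' nats: entropy `S = -sum p ln p`, self-information of the most likely
#' state `Istar = -ln p(n*)`, internal potential energy
#' `U = E[V] = S - Istar`, and free potential energy `F = U - S = -Istar`.
#' The identities `U = S - Istar` and `F = -Istar` hold by construction and
#' are re-verified.
#'
#' @param p an `lmn_distribution`.
#' @param omega network size tag (defaults to the distribution's).
#' @return named list with `omega`, `U`, `S`, `F`, `Istar`, `ground_index`.
#' @export
thermo_point <- function(p, omega = p$omega) {
  stopifnot(inherits(p, "lmn_distribution"))
  pos <- p$p > 0
  S <- -sum(p$p[pos] * log(p$p[pos]))
  land <- if (all(pos)) potential_from_distribution(p) else NULL
  nstar <- if (is.null(land)) which.max(p$p) else land$ground_index
  Istar <- -log(p$p[nstar])
  U <- if (is.null(land)) S - Istar else sum(p$p * land$V)
  F_ <- U - S
  stopifnot(abs(U - (S - Istar)) <= 1e-9 * max(1, abs(U)),
            abs(F_ + Istar) <= 1e-9 * max(1, abs(F_)))
  list(omega = omega, U = U, S = S, F = F_, Istar = Istar,
       ground_index = nstar)
}

#' Thermodynamic profile over a grid of network sizes
#'
#' For each size in `omegas` the model is resized, the stationary
#' distribution solved exactly, and the thermodynamic point computed; the
#' internal pressure `Pi = -dU/dOmega`, pressure `P = dIstar/dOmega`
#' (`= -dF/dOmega`) and bulk modulus `B = Omega * |dP/dOmega|` are then
#' obtained by central finite differences on the grid (one-sided at the
#' endpoints). The profile records, per size, the identity of the ground
#' state ("origin", "macro", or "other"), the potential at the inactive
#' origin and at the macroscopic-well state (the lattice state nearest the
#' macroscopic fixed point `x*`).
#'
#' @param model a [coarse_lmn()].
#' @param omegas increasing grid of at least 5 network sizes.
#' @param xstar optional macroscopic fixed point; computed via
#'   [find_fixed_point()] when `NULL`.
#' @param cap passed to [build_generator()].
#' @return an object of class `lmn_thermo_profile`: a data frame with
#'   columns `omega, N, U, S, F, Istar, Pi, P, B, V_origin, V_macro,
#'   ground`, with the model and `x*` as attributes.
#' @export
sweep_omega <- function(model, omegas, xstar = NULL, cap = 5e5) {
  stopifnot(inherits(model, "coarse_lmn"))
  omegas <- as.numeric(omegas)
  if (length(omegas) < 5 || is.unsorted(omegas, strictly = TRUE)) {
    stop("'omegas' must be a strictly increasing grid of at least 5 sizes")
  }
  if (is.null(xstar)) xstar <- find_fixed_point(model)
  n <- length(omegas)
  cols <- data.frame(omega = omegas, N = NA_integer_, U = NA_real_,
                     S = NA_real_, F = NA_real_, Istar = NA_real_,
                     Pi = NA_real_, P = NA_real_, B = NA_real_,
                     V_origin = NA_real_, V_macro = NA_real_,
                     ground = NA_character_)
  for (i in seq_len(n)) {
    m <- resize(model, omegas[i])
    gen <- tryCatch(build_generator(m, cap = cap),
                    error = function(e) stop("omega = ", omegas[i], ": ",
                                             conditionMessage(e)))
    pst <- solve_stationary(gen)
    tp <- thermo_point(pst, omega = omegas[i])
    land <- potential_from_distribution(pst, strict = FALSE)
    i_origin <- state_to_index(gen$space, rep(0L, m$n_blocks))
    i_macro <- .nearest_lattice_index(gen$space, xstar)
    gr <- land$ground_index
    zg <- gen$space$states[gr, ] / m$sizes
    ground <- if (gr == i_origin) {
      "origin"
    } else if (gr %in% i_macro ||
               sum((zg - xstar)^2) < sum(zg^2)) {
      "macro" # in (or at least nearer to) the macroscopic well
    } else {
      "other"
    }
    cols$N[i] <- sum(m$sizes)
    cols$U[i] <- tp$U; cols$S[i] <- tp$S; cols$F[i] <- tp$F
    cols$Istar[i] <- tp$Istar
    cols$V_origin[i] <- land$V[i_origin]
    cols$V_macro[i] <- land$V[i_macro[1]]
    cols$ground[i] <- ground
  }
  cols$Pi <- -.fd_grid(cols$U, omegas)
  cols$P <- .fd_grid(cols$Istar, omegas)
  cols$B <- omegas * abs(.fd_grid(cols$P, omegas))
  structure(cols, class = c("lmn_thermo_profile", "data.frame"),
            model = model, xstar = xstar)
}

# central differences at interior points, one-sided at endpoints
.fd_grid <- function(y, x) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 2) {
    d[1] <- (y[2] - y[1]) / (x[2] - x[1])
    d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  }
  if (n >= 3) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

# lattice state(s) nearest to a fractional point (Euclidean on fractions,
# ties broken lexicographically via the lowest index)
.nearest_lattice_index <- function(space, xstar) {
  z <- sweep(space$states, 2, space$sizes, "/")
  d2 <- rowSums(sweep(z, 2, xstar, "-")^2)
  which(d2 <= min(d2) + 1e-15)
}

#' Detect the critical network size from a thermodynamic profile
#'
#' Primary detector: the size at which the stationary ground state switches
#' between the macroscopic-well state and the inactive origin, located by
#' linear interpolation of `V(origin) - V(macro)` between the bracketing
#' grid points. Secondary detector: the interior grid point maximizing the
#' bulk modulus `B`. Both are reported together with an agreement flag
#' (within two grid steps).
#'
#' @param profile an [sweep_omega()] result.
#' @return list with `omega_c` (primary; `NA` if no crossing in range),
#'   `omega_c_bulk` (secondary), `agree`, and `monotone` (`TRUE` when the
#'   ground state never switches on the grid).
#' @export
detect_critical_size <- function(profile) {
  stopifnot(inherits(profile, "lmn_thermo_profile"))
  d <- profile$V_origin - profile$V_macro # > 0 supercritical, < 0 subcritical
  om <- profile$omega
  sgn <- sign(d)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0 | d[-length(d)] == 0)
  omega_c <- NA_real_
  if (length(cross) > 0) {
    j <- cross[length(cross)] # the reallocation closest to large sizes
    omega_c <- om[j] - d[j] * (om[j + 1] - om[j]) / (d[j + 1] - d[j])
  }
  interior <- 2:(length(om) - 1)
  omega_b <- om[interior][which.max(profile$B[interior])]
  step <- stats::median(diff(om))
  list(
    omega_c = omega_c,
    omega_c_bulk = omega_b,
    agree = is.finite(omega_c) && abs(omega_c - omega_b) <= 2 * step,
    monotone = length(cross) == 0
  )
}

#' Critical size as a function of a model parameter
#'
#' Applies [sweep_omega()] + [detect_critical_size()] across a family of
#' models indexed by a parameter.
#'
#' @param family function mapping a parameter value to a [coarse_lmn()].
#' @param values parameter grid.
#' @param omegas network-size grid passed to [sweep_omega()].
#' @param ... further arguments to [sweep_omega()].
#' @return data frame with columns `value` and `omega_c` (`NA` where no
#'   critical size lies in range).
#' @export
critical_vs_parameter <- function(family, values, omegas, ...) {
  stopifnot(is.function(family))
  oc <- vapply(values, function(v) {
    prof <- sweep_omega(family(v), omegas, ...)
    detect_critical_size(prof)$omega_c
  }, numeric(1))
  data.frame(value = values, omega_c = oc)
}

#' Export a thermodynamic profile as TSV
#'
#' @param profile an [sweep_omega()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_thermo_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
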