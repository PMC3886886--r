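#' Gain function registry
#'
#' Activation and deactivation propensities of a leaky Markovian network
#' combine a constant leak with a gain function of the net input,
#' `rate_on = (1 - x) * (a + phi(u))` and `rate_off = x * (b + psi(u))`.
#' Gain functions are referenced by name so that model configurations are
#' serializable; this registry maps names to scalar functions (vectorized
#' over their argument) and, optionally, their derivatives (used for
#' analytic Jacobians in the linear noise approximation).
#'
#' Built-in gains:
#' \describe{
#'   \item{`"zero"`}{`u -> 0`, a pure-leak channel.}
#'   \item{`"identity"`}{`u -> u` (must only be used where the net input is
#'     guaranteed nonnegative, as in the SISa model).}
#'   \item{`"tanh_plus"`}{`u -> tanh(u)` for `u > 0`, else 0; the standard
#'     saturating neural response function.}
#' }
#'
#' @param name character scalar, the registered name.
#' @param fn vectorized scalar function, nonnegative on the inputs the model
#'   produces.
#' @param deriv optional derivative of `fn` (vectorized); `NULL` means
#'   finite differences will be used where a derivative is needed.
#' @return `gain_function()` returns the registered function; `gain_deriv()`
#'   the derivative or `NULL`; `list_gains()` the registered names.
#' @examples
#' gain_function("tanh_plus")(c(-1, 0, 1))
#' register_gain("square_plus", function(u) pmax(u, 0)^2,
#'               deriv = function(u) 2 * pmax(u, 0))
#' @export
gain_function <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  g <- .gain_env$fns[[name]]
  if (is.null(g)) {
    stop("unknown gain function '", name, "'; register it with register_gain()")
  }
  g
}

#' @rdname gain_function
#' @export
gain_deriv <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% names(.gain_env$fns)) {
    stop("unknown gain function '", name, "'")
  }
  .gain_env$derivs[[name]]
}

#' @rdname gain_function
#' @export
register_gain <- function(name, fn, deriv = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .gain_env$fns[[name]] <- fn
  .gain_env$derivs[[name]] <- deriv
  invisible(name)
}

#' @rdname gain_function
#' @export
list_gains <- function() sort(names(.gain_env$fns))

.gain_env <- new.env(parent = emptyenv())

# integer codes used by the compiled Gillespie kernel; anything else
# falls back to the interpreted simulator
.gain_code <- function(name) {
  switch(name, zero = 0L, identity = 1L, tanh_plus = 2L, -1L)
}

.register_builtin_gains <- function() {
  .gain_env$fns <- list()
  .gain_env$derivs <- list()
  register_gain("zero", function(u) rep_len(0, length(u)),
                deriv = function(u) rep_len(0, length(u)))
  register_gain("identity", function(u) u,
                deriv = function(u) rep_len(1, length(u)))
  register_gain("tanh_plus", function(u) ifelse(u > 0, tanh(u), 0),
                deriv = function(u) ifelse(u > 0, 1 / cosh(u)^2, 0))
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_gains()
}
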