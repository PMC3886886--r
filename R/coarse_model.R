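#' Coarse-grained (block-homogeneous) leaky Markovian network
#'
#' The fractional activity process: a continuous-time Markov chain on the
#' lattice of per-block active counts `n = (n_1, ..., n_M)`,
#' `0 <= n_k <= N_k`. Block `k` gains an active node at rate
#' `beta_k = (N_k - n_k) * (a_k + phi_k(ubar_k))` and loses one at rate
#' `delta_k = n_k * (b_k + psi_k(ubar_k))`, where
#' `ubar_k = h_k + sum_l Wbar_kl z_l` and `z_l = n_l / N_l`.
#'
#' The network size is `Omega = sum(N_k) / N0`; [resize()] rescales all
#' block sizes while holding the block fractions `nu_k`, the rate
#' parameters, `Wbar` and `h` fixed (coupling acts through fractions, so it
#' is size-invariant). With all leaks positive the chain is irreducible.
#'
#' @param sizes positive integer block sizes `N_k`.
#' @param block_weights `M x M` matrix `Wbar`; `Wbar_kl` is the aggregated
#'   influence of block `l` at full activity on a node of block `k`.
#' @param leak_on,leak_off nonnegative per-block leak rates (recycled).
#' @param gain_on,gain_off registered gain-function names (recycled).
#' @param block_input per-block constant input `h_k` (recycled).
#' @param N0 positive normalizer defining `Omega = sum(sizes) / N0`.
#' @param fractions target block fractions `nu_k` used by [resize()];
#'   default `sizes / sum(sizes)`. Kept separately so that repeated
#'   resizing does not accumulate rounding drift.
#' @param time_unit label, e.g. `"day"` or `"ms"`.
#' @param block_names optional block labels.
#' @param name optional model name.
#' @return an object of class `coarse_lmn`.
#' @examples
#' m <- coarse_lmn(sizes = 50, block_weights = matrix(0.2), leak_on = 1e-4,
#'                 leak_off = 0.055, gain_on = "identity", time_unit = "day")
#' coarse_propensities(m, 10)
#' @export
coarse_lmn <- function(sizes, block_weights, leak_on, leak_off,
                       gain_on = "identity", gain_off = "zero",
                       block_input = 0, N0 = sum(sizes),
                       fractions = NULL, time_unit = "time",
                       block_names = NULL, name = NULL) {
  sizes <- as.integer(round(sizes))
  M <- length(sizes)
  if (any(sizes < 1L)) stop("block sizes must be positive integers")
  block_weights <- matrix(as.numeric(block_weights), M, M)
  leak_on <- rep_len(as.numeric(leak_on), M)
  leak_off <- rep_len(as.numeric(leak_off), M)
  if (any(leak_on < 0) || any(leak_off < 0)) stop("leak rates must be >= 0")
  gain_on <- rep_len(as.character(gain_on), M)
  gain_off <- rep_len(as.character(gain_off), M)
  for (g in unique(c(gain_on, gain_off))) gain_function(g)
  if (!is.null(N0) && N0 <= 0) stop("'N0' must be positive")
  if (is.null(fractions)) fractions <- sizes / sum(sizes)
  fractions <- rep_len(as.numeric(fractions), M)
  fractions <- fractions / sum(fractions)
  if (is.null(block_names)) block_names <- paste0("block", seq_len(M))
  structure(
    list(
      n_blocks = M,
      sizes = sizes,
      fractions = fractions,
      block_weights = block_weights,
      block_input = rep_len(as.numeric(block_input), M),
      leak_on = leak_on, leak_off = leak_off,
      gain_on = gain_on, gain_off = gain_off,
      N0 = as.numeric(N0),
      time_unit = time_unit,
      block_names = block_names,
      name = name
    ),
    class = "coarse_lmn"
  )
}

#' @export
print.coarse_lmn <- function(x, ...) {
  cat("<coarse_lmn>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  blocks:", paste0(x$block_names, " (N=", x$sizes, ")", collapse = ", "), "\n")
  cat("  Omega =", format(network_size(x)), " (N0 =", x$N0, "), time unit:", x$time_unit, "\n")
  invisible(x)
}

#' Network size of a coarse model
#'
#' `Omega = sum(N_k) / N0`, the structural parameter inversely related to
#' the strength of intrinsic noise.
#'
#' @param model a [coarse_lmn()].
#' @return numeric scalar.
#' @export
network_size <- function(model) {
  stopifnot(inherits(model, "coarse_lmn"))
  sum(model$sizes) / model$N0
}

.check_counts <- function(model, counts) {
  counts <- as.numeric(counts)
  if (length(counts) != model$n_blocks ||
      any(counts < 0) || any(counts > model$sizes) ||
      any(counts != round(counts))) {
    stop("'counts' must be integers with 0 <= n_k <= N_k")
  }
  counts
}

#' Coarse net input per block
#'
#' `ubar_k(z) = h_k + sum_l Wbar_kl z_l` evaluated at fractions
#' `z_l = n_l / N_l`.
#'
#' @param model a [coarse_lmn()].
#' @param counts integer active counts per block.
#' @return numeric vector of length `M`.
#' @export
coarse_input <- function(model, counts) {
  counts <- .check_counts(model, counts)
  z <- counts / model$sizes
  drop(model$block_input + model$block_weights %*% z)
}

#' Birth and death propensities of the fractional activity process
#'
#' @inheritParams coarse_input
#' @return list with components `birth` (`beta_k`) and `death` (`delta_k`).
#' @export
coarse_propensities <- function(model, counts) {
  counts <- .check_counts(model, counts)
  u <- coarse_input(model, counts)
  M <- model$n_blocks
  phi <- numeric(M)
  psi <- numeric(M)
  for (k in seq_len(M)) {
    phi[k] <- gain_function(model$gain_on[k])(u[k])
    psi[k] <- gain_function(model$gain_off[k])(u[k])
  }
  list(
    birth = (model$sizes - counts) * (model$leak_on + phi),
    death = counts * (model$leak_off + psi)
  )
}

#' Rescale a coarse model to a new network size
#'
#' New block sizes are `N_k' = max(1, round(omega * N0 * nu_k))` with
#' round-half-even rounding; rate parameters, `Wbar` and `h` are unchanged.
#'
#' @param model a [coarse_lmn()].
#' @param omega new network size, `> 0`.
#' @return a [coarse_lmn()] with rescaled sizes.
#' @export
resize <- function(model, omega) {
  stopifnot(inherits(model, "coarse_lmn"), is.numeric(omega), omega > 0)
  if (omega * model$N0 < model$n_blocks) {
    stop("'omega' too small: total nodes would be fewer than the number of blocks")
  }
  new_sizes <- pmax(1L, as.integer(round(omega * model$N0 * model$fractions)))
  out <- model
  out$sizes <- new_sizes
  out
}

# ---- configuration files -------------------------------------------------

#' Read or write a coarse model configuration
#'
#' Configurations are JSON (default) or YAML files with keys `name`,
#' `time_unit`, `N0`, `omega`, `blocks` (list of
#' `{name, fraction, leak_on, leak_off, gain_on, gain_off, input}`) and
#' `weights` (`M x M` array, row `k` = receiving block). Reading then
#' writing reproduces the model losslessly (numbers serialized at full
#' precision).
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`) or the `format` argument.
#' @param model a [coarse_lmn()].
#' @param format `"json"` or `"yaml"`; default guesses from `path`.
#' @return `read_lmn_config()` returns a [coarse_lmn()];
#'   `write_lmn_config()` returns `path` invisibly.
#' @export
read_lmn_config <- function(path, format = NULL) {
  format <- format %||% .config_format(path)
  cfg <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  }
  blocks <- cfg$blocks
  get <- function(field, default = NULL) {
    vapply(blocks, function(b) {
      v <- b[[field]]
      if (is.null(v)) {
        if (is.null(default)) stop("block missing field '", field, "'")
        v <- default
      }
      v
    }, if (field %in% c("name", "gain_on", "gain_off")) character(1) else numeric(1))
  }
  M <- length(blocks)
  # jsonlite simplifies a nested array to a matrix (already row-oriented);
  # yaml yields a list of row lists
  W <- if (is.matrix(cfg$weights)) {
    matrix(as.numeric(cfg$weights), M, M)
  } else {
    matrix(unlist(cfg$weights), M, M, byrow = TRUE)
  }
  fr <- get("fraction")
  base <- coarse_lmn(
    sizes = rep(1L, M), block_weights = W,
    leak_on = get("leak_on"), leak_off = get("leak_off"),
    gain_on = get("gain_on", "identity"), gain_off = get("gain_off", "zero"),
    block_input = get("input", 0), N0 = cfg$N0, fractions = fr,
    time_unit = cfg$time_unit %||% "time",
    block_names = get("name"), name = cfg$name
  )
  resize(base, cfg$omega %||% 1)
}

#' @rdname read_lmn_config
#' @export
write_lmn_config <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "coarse_lmn"))
  format <- format %||% .config_format(path)
  blocks <- lapply(seq_len(model$n_blocks), function(k) {
    list(
      name = model$block_names[k],
      fraction = model$fractions[k],
      leak_on = model$leak_on[k], leak_off = model$leak_off[k],
      gain_on = model$gain_on[k], gain_off = model$gain_off[k],
      input = model$block_input[k]
    )
  })
  cfg <- list(
    name = model$name, time_unit = model$time_unit,
    N0 = model$N0, omega = network_size(model),
    blocks = blocks,
    weights = apply(model$block_weights, 1, as.list, simplify = FALSE)
  )
  if (format == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the 'yaml' package is required for YAML configs")
    yaml::write_yaml(cfg, path, precision = 17)
  }
  invisible(path)
}

.config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml" else "json"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
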