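#' Node-level leaky Markovian network
#'
#' A continuous-time Markov model of `N` binary nodes. Node `i` activates at
#' rate `(1 - x_i) * (a_i + phi(u_i))` and deactivates at rate
#' `x_i * (b_i + psi(u_i))`, where the net input is
#' `u_i = h_i + sum_j w_ij x_j` and the diagonal of the weight matrix is
#' zero (nodes are not self-regulating). The positive leaks `a_i`, `b_i`
#' keep every transition available regardless of input, which makes the
#' chain irreducible ("leaky").
#'
#' The node-level model scales exponentially in `N` (state space `2^N`) and
#' is intended as a small-`N` validation oracle for the coarse-grained
#' model, not for production-size networks.
#'
#' @param weights `N x N` numeric matrix `W`; `w_ij` is the influence of
#'   node `j` on node `i`. The diagonal must be exactly zero.
#' @param leak_on,leak_off nonnegative per-node leak rates (recycled to
#'   length `N`), in units of `1/time_unit`.
#' @param gain_on,gain_off names of registered gain functions (see
#'   [gain_function()]), recycled to length `N`.
#' @param external_input per-node constant input `h_i` (recycled).
#' @param time_unit label carried through outputs, e.g. `"day"` or `"ms"`.
#' @return an object of class `node_lmn`.
#' @seealso [coarse_grain()], [coarse_lmn()]
#' @export
node_lmn <- function(weights, leak_on, leak_off,
                     gain_on = "identity", gain_off = "zero",
                     external_input = 0, time_unit = "time") {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("'weights' must be a square matrix")
  if (any(diag(weights) != 0)) {
    stop("diagonal of 'weights' must be exactly zero (no self-regulation)")
  }
  leak_on <- rep_len(as.numeric(leak_on), n)
  leak_off <- rep_len(as.numeric(leak_off), n)
  if (any(leak_on < 0) || any(leak_off < 0)) stop("leak rates must be >= 0")
  gain_on <- rep_len(as.character(gain_on), n)
  gain_off <- rep_len(as.character(gain_off), n)
  for (g in unique(c(gain_on, gain_off))) gain_function(g) # validate
  structure(
    list(
      n_nodes = n,
      weights = weights,
      external_input = rep_len(as.numeric(external_input), n),
      leak_on = leak_on, leak_off = leak_off,
      gain_on = gain_on, gain_off = gain_off,
      time_unit = time_unit
    ),
    class = "node_lmn"
  )
}

#' @export
print.node_lmn <- function(x, ...) {
  cat("<node_lmn> ", x$n_nodes, " nodes, time unit: ", x$time_unit, "\n", sep = "")
  invisible(x)
}

.check_binary_state <- function(model, x) {
  if (length(x) != model$n_nodes || !all(x %in% c(0, 1))) {
    stop("'x' must be a binary 0/1 vector of length ", model$n_nodes)
  }
}

#' Net input to a node
#'
#' `u_i = h_i + sum_j w_ij x_j`; the self term vanishes because the weight
#' diagonal is zero.
#'
#' @param model a [node_lmn()] model.
#' @param x binary 0/1 state vector.
#' @param i node index.
#' @return scalar net input.
#' @export
net_input <- function(model, x, i) {
  stopifnot(inherits(model, "node_lmn"))
  .check_binary_state(model, x)
  stopifnot(i >= 1, i <= model$n_nodes)
  model$external_input[i] + sum(model$weights[i, ] * x)
}

#' Node transition propensities
#'
#' Activation and deactivation rates of a single node given the network
#' state: `rate_on = (1 - x_i)(a_i + phi(u_i))`,
#' `rate_off = x_i (b_i + psi(u_i))`. Exactly one of the pair can be
#' nonzero.
#'
#' @inheritParams net_input
#' @return named numeric vector `c(rate_on=, rate_off=)`.
#' @export
node_propensities <- function(model, x, i) {
  u <- net_input(model, x, i) # validates inputs
  phi <- gain_function(model$gain_on[i])
  psi <- gain_function(model$gain_off[i])
  xi <- unname(x[i])
  ron <- (1 - xi) * (model$leak_on[i] + phi(u))
  roff <- xi * (model$leak_off[i] + psi(u))
  c(rate_on = unname(ron), rate_off = unname(roff))
}

#' Coarse grain a node-level model into block counts
#'
#' Partitions the nodes into homogeneous blocks and returns the
#' coarse-grained model on the lattice of per-block active counts. Within
#' each block the leaks, gains and external input must be constant, and the
#' weight `w_ij` may depend only on the block pair of `i` and `j` (off the
#' diagonal). The aggregated block weight is `Wbar_kl = N_l * w(k, l)`, so
#' that the coarse net input `ubar_k(z) = h_k + sum_l Wbar_kl z_l` with
#' `z_l = n_l / N_l` reproduces the node-level input up to the
#' self-exclusion term (a node does not see its own state), an `O(1/N_l)`
#' correction bounded by `max_k |Wbar_kk| / N_k`.
#'
#' @param model a [node_lmn()].
#' @param blocks list of disjoint integer index vectors covering `1:N`.
#' @param N0 normalizing constant for the network size `Omega = N / N0`
#'   (default `N`, i.e. `Omega = 1`).
#' @param tol tolerance for within-block parameter spread.
#' @return a [coarse_lmn()] model.
#' @export
coarse_grain <- function(model, blocks, N0 = model$n_nodes, tol = 1e-8) {
  stopifnot(inherits(model, "node_lmn"), is.list(blocks))
  idx <- unlist(blocks)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(model$n_nodes))) {
    stop("'blocks' must be disjoint index sets covering all nodes")
  }
  M <- length(blocks)
  sizes <- lengths(blocks)
  if (any(sizes < 1L)) stop("every block must contain at least one node")

  check_const <- function(v, what, k) {
    if (diff(range(v)) > tol) {
      stop("block ", k, " is not homogeneous in '", what, "'")
    }
    v[1]
  }
  leak_on <- leak_off <- h <- numeric(M)
  gain_on <- gain_off <- character(M)
  for (k in seq_len(M)) {
    p <- blocks[[k]]
    leak_on[k] <- check_const(model$leak_on[p], "leak_on", k)
    leak_off[k] <- check_const(model$leak_off[p], "leak_off", k)
    h[k] <- check_const(model$external_input[p], "external_input", k)
    if (length(unique(model$gain_on[p])) > 1L) stop("block ", k, " is not homogeneous in 'gain_on'")
    if (length(unique(model$gain_off[p])) > 1L) stop("block ", k, " is not homogeneous in 'gain_off'")
    gain_on[k] <- model$gain_on[p[1]]
    gain_off[k] <- model$gain_off[p[1]]
  }
  Wbar <- matrix(0, M, M)
  for (k in seq_len(M)) {
    for (l in seq_len(M)) {
      w <- model$weights[blocks[[k]], blocks[[l]], drop = FALSE]
      if (k == l) {
        off <- w[row(w) != col(w)]
        if (length(off) && diff(range(off)) > tol) {
          stop("block ", k, " is not homogeneous in 'weights' (within-block)")
        }
        wkl <- if (length(off)) off[1] else 0
      } else {
        if (diff(range(w)) > tol) {
          stop("blocks (", k, ",", l, ") are not homogeneous in 'weights'")
        }
        wkl <- w[1]
      }
      Wbar[k, l] <- sizes[l] * wkl
    }
  }
  coarse_lmn(
    sizes = sizes, block_weights = Wbar,
    leak_on = leak_on, leak_off = leak_off,
    gain_on = gain_on, gain_off = gain_off,
    block_input = h, N0 = N0, time_unit = model$time_unit,
    block_names = names(blocks)
  )
}
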