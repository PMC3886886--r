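#' Lattice state space of the fractional activity process
#'
#' Enumerates the lattice `{0..N_1} x ... x {0..N_M}` of active-count
#' vectors in mixed-radix lexicographic order with `n_1` varying fastest.
#' Index/state maps are mutually inverse bijections over the whole lattice.
#'
#' @param sizes block sizes `N_k`, or a [coarse_lmn()] model.
#' @return an object of class `lattice_space` with fields `sizes`,
#'   `n_states`, and `states` (an `n_states x M` integer matrix whose row
#'   `i` is the count vector of state index `i`).
#' @export
lattice_state_space <- function(sizes) {
  if (inherits(sizes, "coarse_lmn")) sizes <- sizes$sizes
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1))
  card <- prod(sizes + 1)
  if (card > 5e7) stop("lattice too large to enumerate (", card, " states)")
  grids <- lapply(sizes, function(N) 0:N)
  states <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- list(NULL, paste0("n", seq_along(sizes)))
  structure(
    list(sizes = sizes, n_states = as.integer(card), states = states),
    class = "lattice_space"
  )
}

#' @export
print.lattice_space <- function(x, ...) {
  cat("<lattice_space> sizes:", paste(x$sizes, collapse = " x "),
      "->", x$n_states, "states\n")
  invisible(x)
}

#' Convert between state indices and count vectors
#'
#' @param space a [lattice_state_space()].
#' @param counts integer count vector (or matrix, one row per state).
#' @param index 1-based state index (vectorized).
#' @return `state_to_index()` returns integer indices; `index_to_state()`
#'   returns a count matrix with one row per index.
#' @export
state_to_index <- function(space, counts) {
  counts <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  radix <- cumprod(c(1, utils::head(space$sizes + 1, -1)))
  as.integer(counts %*% radix + 1)
}

#' @rdname state_to_index
#' @export
index_to_state <- function(space, index) {
  space$states[index, , drop = FALSE]
}
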