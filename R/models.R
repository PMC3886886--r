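#' Default SISa parameters
#'
#' Reads the shipped SISa configuration (a susceptible-infected-susceptible
#' epidemic with an additional spontaneous infection route, modeling e.g.
#' MRSA colonization in a closed population). The defaults are data, not
#' code: `a` (spontaneous infection, 1/day) and `N0` are pinned by the
#' escape-time law `tau(0) = 1/(N a)` at the inactive state; the recovery
#' rate `g` is set so the critical network size is 0.175; and the
#' transmission rate `beta` is calibrated so the macroscopic endemic fixed
#' point is exactly 0.4719.
#'
#' @return named list with `a`, `beta`, `g`, `N0`, `omega`, `time_unit`.
#' @export
sisa_params <- function() {
  cfg <- jsonlite::read_json(system.file("extdata", "sisa_default.json",
                                         package = "lmnet"),
                             simplifyVector = TRUE)
  cfg[c("a", "beta", "g", "N0", "omega", "time_unit", "name")]
}

#' Build the SISa epidemic model
#'
#' One homogeneous population; per-susceptible infection rate
#' `a + beta * z` (spontaneous plus frequency-dependent transmission from
#' the infected fraction `z`), per-infected recovery rate `g`. As a coarse
#' LMN: `M = 1`, `phi(u) = u`, `psi = 0`, `leak_on = a`, `leak_off = g`,
#' `Wbar = beta`, `h = 0`; macroscopic drift
#' `(1 - x)(a + beta x) - g x`. With `a = 0` the model reduces to the
#' standard SIS model: the origin is absorbing and infections die out for
#' good.
#'
#' @param a spontaneous infection rate (1/day), `>= 0`.
#' @param beta transmission rate at full prevalence (1/day), `>= 0`.
#' @param g recovery rate (1/day), `>= 0`.
#' @param N0 network-size normalizer.
#' @param omega network size; the population is `N = omega * N0`.
#' @return a [coarse_lmn()].
#' @examples
#' m <- build_sisa()                    # shipped defaults
#' find_fixed_point(macro_system(m))    # 0.4719
#' @export
build_sisa <- function(a = sisa_params()$a, beta = sisa_params()$beta,
                       g = sisa_params()$g, N0 = sisa_params()$N0,
                       omega = 1) {
  if (any(c(a, beta, g) < 0)) stop("SISa rates must be nonnegative")
  base <- coarse_lmn(
    sizes = 1L, block_weights = matrix(beta, 1, 1),
    leak_on = a, leak_off = g,
    gain_on = "identity", gain_off = "zero",
    block_input = 0, N0 = N0, fractions = 1,
    time_unit = "day", block_names = "infected", name = "sisa"
  )
  resize(base, omega)
}

#' Default neural-network parameters
#'
#' Reads the shipped excitatory/inhibitory configuration; see
#' [build_nn()].
#'
#' @return named list of NN parameters.
#' @export
nn_params <- function() {
  jsonlite::read_json(system.file("extdata", "nn_default.json",
                                  package = "lmnet"),
                      simplifyVector = TRUE)
}

#' Build the two-population excitatory/inhibitory neural-network model
#'
#' Two homogeneous populations of excitatory (E) and inhibitory (I)
#' neurons. Every neuron receives the same net input
#' `u = h + w_E z_E - w_I z_I` (excitation positive, inhibition negative)
#' and activates at rate `leak + response(u)` (default response
#' `tanh_plus`: `tanh` clipped at zero); active neurons deactivate at the
#' constant rate `alpha`. The strictly positive activation leak keeps the
#' chain irreducible even when inhibition silences the response. The
#' network is "balanced" when `w_E` is close to `w_I`: the balance
#' diagnostic `w_E - w_I` (net recurrent gain, which sets the up-state
#' fixed point) and `w_E + w_I` (the scale of the opposing drives) are
#' attached as the attribute `balance`.
#'
#' @param w_E,w_I nonnegative coupling weights of the E and I populations
#'   at full activity.
#' @param h external input (dimensionless drive through the response
#'   function).
#' @param alpha deactivation rate (1/ms).
#' @param leak spontaneous activation leak (1/ms), `> 0` for
#'   irreducibility.
#' @param response registered gain-function name.
#' @param ei_ratio length-2 integer ratio of excitatory to inhibitory
#'   population sizes (default 1:1; some cortical areas are closer to
#'   4:1).
#' @param N0 network-size normalizer (total neurons at `omega = 1`).
#' @param omega network size.
#' @return a [coarse_lmn()] with blocks `E`, `I`.
#' @export
build_nn <- function(w_E = nn_params()$w_E, w_I = nn_params()$w_I,
                     h = nn_params()$h, alpha = nn_params()$alpha,
                     leak = nn_params()$leak,
                     response = nn_params()$response,
                     ei_ratio = c(1, 1), N0 = nn_params()$N0,
                     omega = 1) {
  if (any(c(w_E, w_I, alpha, leak) < 0)) stop("NN rates/weights must be nonnegative")
  fr <- ei_ratio / sum(ei_ratio)
  W <- matrix(c(w_E, w_E, -w_I, -w_I), 2, 2) # rows: receiving E, I
  base <- coarse_lmn(
    sizes = c(1L, 1L), block_weights = W,
    leak_on = leak, leak_off = alpha,
    gain_on = response, gain_off = "zero",
    block_input = h, N0 = N0, fractions = fr,
    time_unit = "ms", block_names = c("E", "I"), name = "nn"
  )
  m <- resize(base, omega)
  attr(m, "balance") <- c(net_gain = w_E - w_I, drive_scale = w_E + w_I)
  m
}

#' Random small fixture models for property tests
#'
#' A seeded suite of block-homogeneous node-level models (1 or 2 blocks,
#' at most `max_size` nodes per block) with strictly positive leaks (hence
#' irreducible chains) and gain functions chosen so propensities stay
#' nonnegative, together with their partitions and coarse-grained
#' counterparts.
#'
#' @param seed integer seed.
#' @param n number of models.
#' @param max_size maximum nodes per block.
#' @return list of entries `list(node =, blocks =, coarse =)`.
#' @export
fixture_models <- function(seed = 1, n = 10, max_size = 8) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    M <- sample(1:2, 1)
    sizes <- sample(2:max_size, M, replace = TRUE)
    gain_on <- sample(c("tanh_plus", "identity", "zero"), M, replace = TRUE)
    # identity gain requires nonnegative inputs
    wsign <- ifelse(gain_on == "identity", 0, -0.3)
    w <- matrix(stats::runif(M * M, wsign, 0.6), M, M)
    h <- ifelse(gain_on == "identity", stats::runif(M, 0, 0.3),
                stats::runif(M, -0.2, 0.3))
    a <- stats::runif(M, 0.2, 1.2)
    b <- stats::runif(M, 0.2, 1.2)
    N <- sum(sizes)
    blocks <- split(seq_len(N), rep(seq_len(M), sizes))
    Wnode <- matrix(0, N, N)
    for (k in seq_len(M)) {
      for (l in seq_len(M)) {
        Wnode[blocks[[k]], blocks[[l]]] <- w[k, l] / sizes[l]
      }
    }
    diag(Wnode) <- 0
    node <- node_lmn(
      weights = Wnode,
      leak_on = rep(a, sizes), leak_off = rep(b, sizes),
      gain_on = rep(gain_on, sizes), gain_off = "zero",
      external_input = rep(h, sizes)
    )
    out[[i]] <- list(node = node, blocks = blocks,
                     coarse = coarse_grain(node, blocks))
  }
  out
}

#' Exact stationary distribution of a node-level model (oracle)
#'
#' Brute-force construction of the `2^N`-state generator and stationary
#' solve; only intended for tiny validation models (`N <= 12`).
#'
#' @param model a [node_lmn()].
#' @return list with `states` (binary matrix) and `p`.
#' @export
node_stationary <- function(model) {
  stopifnot(inherits(model, "node_lmn"))
  N <- model$n_nodes
  if (N > 12) stop("node-level solve is a small-N validation oracle (N <= 12)")
  states <- as.matrix(expand.grid(rep(list(0:1), N)))
  ns <- nrow(states)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (s in seq_len(ns)) {
    x <- states[s, ]
    for (i in seq_len(N)) {
      pr <- node_propensities(model, x, i)
      rate <- if (x[i] == 0) pr["rate_on"] else pr["rate_off"]
      if (rate > 0) {
        ii <- c(ii, s)
        jj <- c(jj, s + (1 - 2 * x[i]) * 2^(i - 1))
        xx <- c(xx, rate)
      }
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ns, ns))
  Matrix::diag(Q) <- -Matrix::rowSums(Q)
  A <- Matrix::t(Q)
  A[ns, ] <- 1
  p <- as.numeric(Matrix::solve(A, c(rep(0, ns - 1), 1)))
  p[p < 0] <- 0
  list(states = states, p = p / sum(p))
}
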