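# shared fixtures, all built in code

# a single node with on/off leak rates a, b: the two-state chain
two_state <- function(a = 1, b = 3) {
  coarse_lmn(sizes = 1, block_weights = matrix(0), leak_on = a, leak_off = b,
             gain_on = "zero", gain_off = "zero")
}

# N exchangeable zero-coupling nodes: stationary law Binomial(N, a/(a+b))
zero_coupling <- function(N, a = 0.4, b = 0.6) {
  coarse_lmn(sizes = N, block_weights = matrix(0), leak_on = a, leak_off = b,
             gain_on = "zero", gain_off = "zero")
}

# small asymmetric two-block model (non-equilibrium at stationarity)
two_block_asym <- function(sizes = c(2, 2)) {
  coarse_lmn(sizes = sizes,
             block_weights = matrix(c(0.5, -0.4, 0.9, 0), 2, 2),
             leak_on = c(0.3, 0.6), leak_off = c(0.8, 0.5),
             gain_on = "tanh_plus", gain_off = "zero",
             block_input = c(0.2, -0.1))
}

# birth/death rate vectors of a one-block model, for the closed-form oracle
bd_rates <- function(model) {
  stopifnot(model$n_blocks == 1)
  N <- model$sizes
  birth <- vapply(0:(N - 1), function(n) coarse_propensities(model, n)$birth,
                  numeric(1))
  death <- vapply(1:N, function(n) coarse_propensities(model, n)$death,
                  numeric(1))
  list(birth = birth, death = death)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# random strictly positive probability vector
random_distribution <- function(n) {
  w <- stats::rexp(n) + 1e-6
  p <- w / sum(w)
  .lmn_dist <- lmnet:::.new_distribution
  .lmn_dist(p, lattice_state_space(n - 1), time = "test")
}
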