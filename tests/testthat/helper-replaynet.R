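# Shared fixtures and independent oracles.

default_p <- neuron_params()

tiny_net <- function(kind = "nDL", N = 10, K = 8, seed = 42,
                     params = default_p) {
  set.seed(seed)
  w <- network_weights(N, K, kind, n_inh = N)
  list(weights = w, state = network_state(w, params), params = params)
}

# brute-force kernel-convolution oracle for the presynaptic trace: the
# trace at step t is the sum of exp(-(t - t') * dt / tau) over all spike
# steps t' <= t
trace_convolution_oracle <- function(spikes, dt, tau) {
  n <- length(spikes)
  out <- numeric(n)
  for (t in seq_len(n)) {
    tt <- which(spikes[seq_len(t)] == 1)
    out[t] <- sum(exp(-(t - tt) * dt / tau))
  }
  out
}

# instantaneous KL-divergence integrand between Poisson rates f and the
# afferent rate prediction phi(W x); the W rule must equal its negative
# gradient up to the constant prefactor eta / (g * beta0 * phi0)
kl_integrand <- function(W, f, x, params = default_p) {
  phi <- static_sigmoid(drop(W %*% x), params)
  sum(f * log(f / phi) - f + phi)
}

kl_gradient_fd <- function(W, f, x, params = default_p, eps = 1e-6) {
  grad <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    Wp <- W; Wp[i, j] <- W[i, j] + eps
    Wm <- W; Wm[i, j] <- W[i, j] - eps
    grad[i, j] <- (kl_integrand(Wp, f, x, params) -
                     kl_integrand(Wm, f, x, params)) / (2 * eps)
  }
  grad
}

# deterministic, trial-averaged synthetic rate table for assignment tests
synthetic_assignment <- function(sizes, n_stimuli = length(sizes)) {
  rates <- do.call(rbind, lapply(seq_along(sizes), function(j) {
    m <- matrix(1, sizes[j], n_stimuli)
    m[, j] <- 40
    m
  }))
  assign_assemblies(rates)
}
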