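#' Initialize the synaptic matrices of a network variant
#'
#' Creates the weight container for one of the three model variants:
#' \describe{
#'   \item{`"nDL"`}{mixed-sign afferent `W` (N x K) and recurrent `M`
#'     (N x N), plus a non-negative inhibitory-only matrix `G`. `W` and `M`
#'     are initialized from zero-mean Gaussians with variances
#'     `init_scale / sqrt(K)` and `init_scale / sqrt(N)`; `G` starts
#'     uniformly at `1 / sqrt(N)`.}
#'   \item{`"signed"`}{sign-constrained recurrent synapses: each ordered
#'     neuron pair is randomly and permanently assigned to the excitatory
#'     matrix `M_exc` (probability 1/2), the prediction-error inhibitory
#'     matrix `M_inh` (1/4), or the balancing inhibitory matrix `G` (1/4).
#'     All three are non-negative at all times; `W` stays mixed-sign.}
#'   \item{`"DL"`}{distinct excitatory (`n_neurons`) and inhibitory
#'     (`n_inh`) populations obeying Dale's law. Each postsynaptic
#'     population X has signed afferents `W_X`, excitatory recurrents
#'     `M_XE`, and two inhibitory paths `G1_XI` (predicting alone) and
#'     `G2_XI` (predicting jointly with excitation).}
#' }
#'
#' Matrices are drawn from the current RNG stream; set the seed beforehand
#' for reproducibility. Self-connections are allowed and plastic.
#'
#' @param n_neurons number of network neurons (excitatory pool size for
#'   `"DL"`).
#' @param n_inputs number of afferent input neurons K.
#' @param kind model variant.
#' @param n_inh inhibitory pool size (`"DL"` only).
#' @param init_scale scale of the Gaussian initializer variances.
#' @param w_mask optional 0/1 matrix (N x K) restricting which afferent
#'   synapses exist and learn (used by the two-subnetwork conditioned
#'   protocol); masked-out entries start and stay at zero.
#' @return An object of class `network_weights`.
#' @export
network_weights <- function(n_neurons, n_inputs,
                            kind = c("nDL", "signed", "DL"),
                            n_inh = n_neurons, init_scale = 0.1,
                            w_mask = NULL) {
  kind <- match.arg(kind)
  N <- as.integer(n_neurons); K <- as.integer(n_inputs)
  stopifnot(N > 0, K > 0)
  sd_w <- sqrt(init_scale / sqrt(K))
  sd_m <- sqrt(init_scale / sqrt(N))
  gauss <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

  if (!is.null(w_mask)) {
    stopifnot(identical(dim(w_mask), c(N, K)))
    w_mask <- (w_mask != 0) * 1
  }
  mask_W <- function(W) if (is.null(w_mask)) W else W * w_mask

  w <- switch(kind,
    nDL = list(
      W = mask_W(gauss(N, K, sd_w)),
      M = gauss(N, N, sd_m),
      G = matrix(1 / sqrt(N), N, N)
    ),
    signed = {
      # fixed random partition of ordered pairs: 1/2 exc, 1/4 M_inh, 1/4 G
      lab <- matrix(sample.int(4L, N * N, replace = TRUE), N, N)
      mask_e <- (lab <= 2L) * 1
      mask_i <- (lab == 3L) * 1
      mask_g <- (lab == 4L) * 1
      list(
        W = mask_W(gauss(N, K, sd_w)),
        M_exc = abs(gauss(N, N, sd_m)) * mask_e,
        M_inh = abs(gauss(N, N, sd_m)) * mask_i,
        G = (1 / sqrt(N)) * mask_g,
        mask_exc = mask_e, mask_inh = mask_i, mask_g = mask_g
      )
    },
    DL = {
      NI <- as.integer(n_inh)
      stopifnot(NI > 0)
      sd_me <- sqrt(init_scale / sqrt(N))
      list(
        W_E = gauss(N, K, sd_w), W_I = gauss(NI, K, sd_w),
        M_EE = abs(gauss(N, N, sd_me)), M_IE = abs(gauss(NI, N, sd_me)),
        G1_EI = matrix(1 / sqrt(NI), N, NI),
        G2_EI = matrix(1 / sqrt(NI), N, NI),
        G1_II = matrix(1 / sqrt(NI), NI, NI),
        G2_II = matrix(1 / sqrt(NI), NI, NI)
      )
    })

  structure(c(w, list(kind = kind, n_neurons = N, n_inputs = K,
                      n_inh = if (kind == "DL") as.integer(n_inh) else NA_integer_,
                      w_mask = w_mask)),
            class = "network_weights")
}

#' @export
print.network_weights <- function(x, ...) {
  cat(sprintf("Network weights (%s): N = %d, K = %d", x$kind, x$n_neurons,
              x$n_inputs))
  if (x$kind == "DL") cat(sprintf(", N_I = %d", x$n_inh))
  cat("\n  matrices:", paste(weight_matrix_names(x), collapse = ", "), "\n")
  invisible(x)
}

weight_matrix_names <- function(weights) {
  switch(weights$kind,
         nDL = c("W", "M", "G"),
         signed = c("W", "M_exc", "M_inh", "G"),
         DL = c("W_E", "W_I", "M_EE", "M_IE", "G1_EI", "G2_EI", "G1_II",
                "G2_II"))
}

#' Initial per-neuron state of a network
#'
#' Zero presynaptic traces and membrane potentials, homeostatic variable
#' `h = theta0` (so the dynamic response function starts identical to the
#' static one), time 0.
#'
#' @param weights a [network_weights()] object.
#' @param params a [neuron_params()] object.
#' @return An object of class `network_state` with fields `x`, `y` (for
#'   `"DL"`, `y` and `h` are lists with elements `E` and `I`), `h`, `u`,
#'   `f`, `spikes`, and `t`.
#' @export
network_state <- function(weights, params = neuron_params()) {
  N <- weights$n_neurons; K <- weights$n_inputs
  if (weights$kind == "DL") {
    NI <- weights$n_inh
    st <- list(x = numeric(K),
               y = list(E = numeric(N), I = numeric(NI)),
               h = list(E = rep(params$theta0, N), I = rep(params$theta0, NI)),
               u = list(E = numeric(N), I = numeric(NI)),
               f = list(E = numeric(N), I = numeric(NI)),
               spikes = list(E = integer(N), I = integer(NI)),
               t = 0)
  } else {
    st <- list(x = numeric(K), y = numeric(N), h = rep(params$theta0, N),
               u = numeric(N), f = numeric(N), spikes = integer(N), t = 0)
  }
  structure(st, class = "network_state")
}

#' Membrane potentials and component predictions
#'
#' Computes the membrane potential of every neuron from the presynaptic
#' traces, together with the component potentials that each connection class
#' contributes (the "predictions" consumed by the plasticity rules):
#' \itemize{
#'   \item nDL: `u = W x + (M - G) y`; components `W`, `M`, `G`.
#'   \item signed: `u = W x + (M_exc - M_inh) y - G y`; components `W`,
#'     `M_exc`, `M_inh`, `M` (their joint difference), `G`.
#'   \item DL (per population X): `u = W_X x + M_XE yE - G2_XI yI -
#'     G1_XI yI`; components `W`, `M2` (joint path-2), `M1` (path 1).
#' }
#'
#' @param weights a [network_weights()] object.
#' @param x afferent traces (length K).
#' @param y recurrent traces (length N, or `list(E =, I =)` for `"DL"`).
#' @return `list(u =, v =)`; for `"DL"` both are lists over populations.
#' @examples
#' w <- structure(list(W = matrix(2), M = matrix(0), G = matrix(1),
#'                     kind = "nDL", n_neurons = 1L, n_inputs = 1L),
#'                class = "network_weights")
#' membrane_potential(w, x = 0.5, y = 1)$u  # 2*0.5 - 1 = 0
#' @export
membrane_potential <- function(weights, x, y) {
  K <- weights$n_inputs
  if (length(x) != K) stop("afferent trace length does not match K")
  if (weights$kind == "nDL") {
    if (length(y) != weights$n_neurons)
      stop("recurrent trace length does not match N")
    vW <- drop(weights$W %*% x)
    vM <- drop(weights$M %*% y)
    vG <- drop(weights$G %*% y)
    list(u = vW + vM - vG, v = list(W = vW, M = vM, G = vG))
  } else if (weights$kind == "signed") {
    if (length(y) != weights$n_neurons)
      stop("recurrent trace length does not match N")
    vW <- drop(weights$W %*% x)
    ve <- drop(weights$M_exc %*% y)
    vi <- drop(weights$M_inh %*% y)
    vG <- drop(weights$G %*% y)
    list(u = vW + ve - vi - vG,
         v = list(W = vW, M_exc = ve, M_inh = vi, M = ve - vi, G = vG))
  } else {
    if (!is.list(y) || !all(c("E", "I") %in% names(y)))
      stop("DL model requires y = list(E =, I =)")
    out <- lapply(c(E = "E", I = "I"), function(X) {
      vW <- drop(weights[[paste0("W_", X)]] %*% x)
      v2 <- drop(weights[[paste0("M_", X, "E")]] %*% y$E) -
        drop(weights[[paste0("G2_", X, "I")]] %*% y$I)
      v1 <- drop(weights[[paste0("G1_", X, "I")]] %*% y$I)
      list(u = vW + v2 - v1, v = list(W = vW, M2 = v2, M1 = v1))
    })
    list(u = lapply(out, `[[`, "u"), v = lapply(out, `[[`, "v"))
  }
}

#' Bernoulli spike sampling from instantaneous rates
#'
#' Draws one spike indicator per neuron with probability `f * dt / 1000`,
#' the standard discretization of an inhomogeneous Poisson process at small
#' `dt`. Uses the current RNG stream (one uniform per neuron, in order).
#'
#' @param f rates in Hz, `0 <= f <= phi0`.
#' @param dt time step (ms).
#' @param params a [neuron_params()] object (rate ceiling check).
#' @return integer 0/1 vector of spikes.
#' @export
sample_spikes <- function(f, dt = params$dt, params = neuron_params()) {
  stopifnot(all(f >= 0), all(f <= params$phi0))
  p <- f * dt / 1000
  stopifnot(all(p <= 1))
  as.integer(stats::runif(length(f)) < p)
}

#' One Euler step of the network dynamics
#'
#' Advances the network state by `dt`: updates the afferent traces from the
#' input spikes (treated as all-zero in spontaneous mode), computes membrane
#' potentials, updates the homeostatic variable from the current-step
#' potential, evaluates the dynamic response function, samples spikes, and
#' finally updates the recurrent traces from those spikes. Weights are not
#' modified; see the `update_*` plasticity functions.
#'
#' RNG draw order per step (matching the compiled engine): `K` uniforms are
#' consumed by the caller-supplied input spikes, then `N` uniforms here for
#' the network spikes (`N_E` then `N_I` for `"DL"`).
#'
#' @param state a [network_state()] object.
#' @param weights a [network_weights()] object.
#' @param input_spikes 0/1 vector of length K (ignored when
#'   `mode = "spontaneous"`).
#' @param params a [neuron_params()] object.
#' @param mode `"evoked"` (input drives the afferent traces) or
#'   `"spontaneous"` (afferent traces decay to zero).
#' @param fixed_h if `TRUE` the homeostatic variable is frozen (ablation).
#' @return the updated `network_state`, with fields `u`, `f`, `spikes`, and
#'   the potential components in attribute `"v"`.
#' @export
step_network <- function(state, weights, input_spikes,
                         params = neuron_params(),
                         mode = c("evoked", "spontaneous"),
                         fixed_h = FALSE) {
  mode <- match.arg(mode)
  if (mode == "spontaneous") input_spikes <- integer(weights$n_inputs)
  if (length(input_spikes) != weights$n_inputs)
    stop("input_spikes length does not match K")
  state$x <- decay_and_jump_trace(state$x, input_spikes, params$dt, params$tau)

  mp <- membrane_potential(weights, state$x, state$y)
  if (weights$kind == "DL") {
    if (!all(is.finite(c(mp$u$E, mp$u$I))))
      stop("non-finite membrane potential at t = ", state$t)
    for (X in c("E", "I")) {
      state$u[[X]] <- mp$u[[X]]
      if (!fixed_h) state$h[[X]] <- update_h(state$h[[X]], mp$u[[X]], params)
      state$f[[X]] <- dynamic_sigmoid(mp$u[[X]], state$h[[X]], params)
    }
    state$spikes$E <- sample_spikes(state$f$E, params$dt, params)
    state$spikes$I <- sample_spikes(state$f$I, params$dt, params)
    state$y$E <- decay_and_jump_trace(state$y$E, state$spikes$E, params$dt,
                                      params$tau)
    state$y$I <- decay_and_jump_trace(state$y$I, state$spikes$I, params$dt,
                                      params$tau)
  } else {
    if (!all(is.finite(mp$u)))
      stop("non-finite membrane potential at t = ", state$t)
    state$u <- mp$u
    if (!fixed_h) state$h <- update_h(state$h, mp$u, params)
    state$f <- dynamic_sigmoid(mp$u, state$h, params)
    state$spikes <- sample_spikes(state$f, params$dt, params)
    state$y <- decay_and_jump_trace(state$y, state$spikes, params$dt,
                                    params$tau)
  }
  state$t <- state$t + params$dt
  attr(state, "v") <- mp$v
  state
}
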