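test_that("parameter validation rejects non-physical constants", {
  expect_error(neuron_params(dt = -1), "dt")
  expect_error(neuron_params(tau_h = 10), "tau_h")
  expect_error(neuron_params(phi0 = 0), "phi0")
  expect_error(neuron_params(h_floor = 0), "h_floor")
  expect_error(neuron_params(dt = 25), "probability")
})

test_that("trace update matches the closed-form kernel", {
  expect_equal(decay_and_jump_trace(1, FALSE, dt = 15, tau = 15), exp(-1))
  expect_equal(decay_and_jump_trace(0, TRUE, dt = 3, tau = 12), 1)
  expect_equal(decay_and_jump_trace(0.5, TRUE, dt = 1, tau = 15),
               0.5 * exp(-1 / 15) + 1)
  expect_equal(decay_and_jump_trace(0.5, TRUE, dt = 1, tau = 15),
               1.46775349252, tolerance = 1e-9)
  expect_error(decay_and_jump_trace(1, FALSE, dt = -1, tau = 15))
  expect_error(decay_and_jump_trace(1, FALSE, dt = 1, tau = 0))
})

test_that("iterated trace equals the brute-force spike-train convolution", {
  set.seed(7)
  for (rep in 1:3) {
    spikes <- as.integer(runif(1000) < 0.05)
    tr <- 0
    stepwise <- numeric(1000)
    for (t in 1:1000) {
      tr <- decay_and_jump_trace(tr, spikes[t], dt = 1, tau = 15)
      stepwise[t] <- tr
    }
    expect_equal(stepwise, trace_convolution_oracle(spikes, 1, 15),
                 tolerance = 1e-10)
  }
})

test_that("static sigmoid has the printed midpoint, slope and limits", {
  p <- default_p
  expect_equal(static_sigmoid(p$g * p$theta0, p), p$phi0 / 2)
  expect_equal(static_sigmoid(-1e3, p), 0)
  expect_equal(static_sigmoid(1e3, p), p$phi0)
  # closed-form value at rest
  expect_equal(static_sigmoid(0, p), 50 / (1 + exp(45)), tolerance = 1e-12)
  expect_equal(static_sigmoid(0, p), 1.431259e-18, tolerance = 1e-5)
})

test_that("dynamic sigmoid reduces to the static one at h = 1 and shifts
           its midpoint with h", {
  p <- default_p
  u <- seq(-5, 8, by = 0.25)
  expect_equal(dynamic_sigmoid(u, 1, p), static_sigmoid(u, p))
  expect_equal(dynamic_sigmoid(4, 1, p), 50 / (1 + exp(-15)),
               tolerance = 1e-12)
  for (h in c(0.2, 1, 2.5)) {
    expect_equal(dynamic_sigmoid(p$g * p$theta0 * h, h, p), p$phi0 / 2)
    f <- dynamic_sigmoid(u, h, p)
    expect_true(all(diff(f) >= 0))      # monotone in u
    expect_true(all(f >= 0 & f <= p$phi0))
    # strictly inside the range near the midpoint
    un <- p$g * p$theta0 * h + c(-0.2, 0, 0.2)
    fn <- dynamic_sigmoid(un, h, p)
    expect_true(all(diff(fn) > 0) && all(fn > 0 & fn < p$phi0))
  }
  expect_warning(dynamic_sigmoid(0, 1e-6, p), "clamped")
})

test_that("homeostatic variable decays slowly, rises toward the
           threshold-normalized potential, and respects the floor", {
  p <- default_p
  expect_equal(update_h(2, 1, p), 2 * exp(-1e-4))
  # rise branch: relaxation toward u / (g * theta0)
  h1 <- update_h(1, 6, p)
  expect_equal(h1, 1 + (2 - 1) * (1 - exp(-1 / 1000)))
  expect_true(h1 > 1 && h1 < 2)
  # floor clamp
  expect_equal(update_h(p$h_floor, -100, p), p$h_floor)
  expect_error(update_h(1e-9, 0, p))
})

test_that("h is a decreasing envelope between upward excursions", {
  p <- default_p
  h <- 1
  us <- c(rep(0, 500), 9, rep(0, 500))  # one excursion in a silent stretch
  hs <- numeric(length(us))
  for (i in seq_along(us)) {
    h <- update_h(h, us[i], p)
    hs[i] <- h
  }
  expect_true(all(diff(hs[1:500]) < 0))        # decay before
  expect_gt(hs[501], hs[500])                  # jump at the excursion
  expect_true(all(diff(hs[502:1001]) < 0))     # decay after
})

test_that("membrane potential combines the connection classes per variant", {
  # zero weights -> zero everywhere
  net <- tiny_net("nDL")
  mp <- membrane_potential(net$weights, numeric(8) + 1, numeric(10) + 1)
  expect_equal(mp$u, mp$v$W + mp$v$M - mp$v$G)

  w0 <- net$weights
  w0$W[] <- 0; w0$M[] <- 0; w0$G[] <- 0
  expect_equal(membrane_potential(w0, rep(1, 8), rep(1, 10))$u, rep(0, 10))

  # hand example: u = 2 * 0.5 - 1 = 0
  w1 <- net$weights
  w1$n_inputs <- 1L; w1$n_neurons <- 1L
  w1$W <- matrix(2); w1$M <- matrix(0); w1$G <- matrix(1)
  expect_equal(membrane_potential(w1, 0.5, 1)$u, 0)

  # signed variant: identical M_exc and M_inh cancel exactly
  snet <- tiny_net("signed")
  sw <- snet$weights
  sw$M_exc <- matrix(0.3, 10, 10)
  sw$M_inh <- matrix(0.3, 10, 10)
  mp <- membrane_potential(sw, rep(0, 8), runif(10))
  expect_equal(mp$v$M, rep(0, 10))

  expect_error(membrane_potential(net$weights, rep(1, 5), rep(1, 10)),
               "afferent")
})

test_that("spike sampling is a seeded Bernoulli thinning with the right
           long-run rate", {
  p <- default_p
  expect_equal(sample_spikes(numeric(20), params = p), integer(20))
  set.seed(123)
  a <- sample_spikes(rep(30, 50), params = p)
  set.seed(123)
  b <- sample_spikes(rep(30, 50), params = p)
  expect_identical(a, b)
  # law of large numbers at 50 Hz over 1e5 steps: 3-sigma band ~ 0.65 Hz
  set.seed(9)
  n <- 1e5
  hits <- sum(stats::runif(n) < 50 / 1000)
  rate <- hits / n * 1000
  expect_lt(abs(rate - 50), 3 * sqrt(0.05 * 0.95 / n) * 1000)
  expect_error(sample_spikes(rep(60, 3), params = p))
  expect_error(sample_spikes(rep(-1, 3), params = p))
})

test_that("a network step is consistent with its component operations", {
  p <- default_p
  net <- tiny_net("nDL", seed = 5)
  w0 <- net$weights
  w0$W[] <- 0; w0$M[] <- 0; w0$G[] <- 0
  st <- step_network(net$state, w0, integer(8), p)
  expect_equal(st$f, dynamic_sigmoid(rep(0, 10), st$h, p))
  expect_equal(st$t, p$dt)

  # spontaneous mode ignores the supplied input spikes
  set.seed(11)
  s1 <- step_network(net$state, net$weights, rep(1L, 8), p,
                     mode = "spontaneous")
  set.seed(11)
  s2 <- step_network(net$state, net$weights, integer(8), p,
                     mode = "spontaneous")
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$x, s2$x)

  # rates stay within [0, phi0] over a driven stretch
  set.seed(21)
  st <- net$state
  for (i in 1:200) {
    st <- step_network(st, net$weights, as.integer(runif(8) < 0.3), p)
    expect_true(all(st$f >= 0 & st$f <= p$phi0))
    expect_true(all(st$x >= 0), all(st$y >= 0))
  }

  # with u pinned below h, h decays toward the floor on the tau_h scale
  st <- net$state
  st$h <- rep(0.5, 10)
  for (i in 1:2000) st <- step_network(st, w0, integer(8), p)
  expect_equal(st$h, rep(0.5 * exp(-2000 / p$tau_h), 10), tolerance = 1e-9)
})

test_that("non-finite potentials abort with a diagnostic", {
  p <- default_p
  net <- tiny_net("nDL")
  net$weights$W[1, 1] <- Inf
  expect_error(step_network(net$state, net$weights, rep(1L, 8), p),
               "non-finite")
})
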