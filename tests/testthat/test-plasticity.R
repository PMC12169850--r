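test_that("error term vanishes at the fixed point, saturates away, and
           matches the hand-computed value", {
  p <- default_p
  phi3 <- static_sigmoid(3, p)
  expect_equal(error_term(phi3, 3, p), 0)
  expect_equal(error_term(50, 3, p), 0.25)
  expect_equal(error_term(10, 1e3, p), 0)  # saturation factor kills it
  expect_lt(error_term(1, 3, p), 0)        # sign follows f - phi(v)
  expect_gt(error_term(40, 3, p), 0)
  expect_error(error_term(60, 3, p))
})

test_that("nDL rules gate on the presynaptic trace and stop at the fixed
           point", {
  p <- default_p
  W <- matrix(0.1, 4, 3)
  f <- c(50, 20, 10, 5)
  vW <- rep(3, 4)
  expect_equal(update_W(W, f, vW, numeric(3), params = p), W)
  expect_equal(update_W(W, static_sigmoid(vW, p), vW, runif(3), params = p),
               W)
  # direct product: eta * 0.25 * 1
  W1 <- update_W(matrix(0, 1, 1), 50, 3, 1, eta = 1e-4, params = p)
  expect_equal(W1[1, 1], 2.5e-5)

  M <- matrix(0.05, 4, 4)
  expect_equal(update_M_nDL(M, f, rep(3, 4), numeric(4), params = p), M)
  # under-predicted postsynaptic rate with active presynaptic partner
  M2 <- update_M_nDL(M, rep(40, 4), rep(3, 4), rep(1, 4), params = p)
  expect_true(all(M2 > M))
  # over-predicted: depression
  M3 <- update_M_nDL(M, rep(5, 4), rep(3, 4), rep(1, 4), params = p)
  expect_true(all(M3 < M))
})

test_that("two co-active neurons above their recurrent predictions grow
           mutual excitation", {
  p <- default_p
  M <- matrix(0, 2, 2)
  y <- c(0.8, 0.8)       # both recently active
  f <- c(45, 45)         # firing above the prediction phi(0) ~ 0
  M1 <- update_M_nDL(M, f, drop(M %*% y), y, params = p)
  expect_gt(M1[1, 2], 0)
  expect_gt(M1[2, 1], 0)
})

test_that("G stays non-negative under depression and freezes at its fixed
           point", {
  p <- default_p
  G <- matrix(0, 3, 3)
  # negative update at the zero bound stays clamped
  G1 <- update_G_nDL(G, rep(0, 3), rep(3, 3), rep(1, 3), params = p)
  expect_equal(G1, G)
  G2 <- matrix(0.2, 3, 3)
  vG <- drop(G2 %*% rep(0.5, 3))
  expect_equal(update_G_nDL(G2, static_sigmoid(vG, p), vG, rep(0.5, 3),
                            params = p), G2)
  # within-assembly direction: high f, under-predicting vG, active partner
  G3 <- update_G_nDL(G2, rep(48, 3), vG, rep(0.5, 3), params = p)
  expect_true(all(G3 > G2))
})

test_that("W rule equals the finite-difference KL gradient up to the
           constant prefactor", {
  p <- default_p
  set.seed(31)
  for (rep in 1:5) {
    W <- matrix(rnorm(9, 0, 0.3), 3, 3)
    x <- runif(3, 0.2, 1)
    f <- runif(3, 5, 45)
    dW <- update_W(W, f, drop(W %*% x), x, eta = p$eta, params = p) - W
    grad <- kl_gradient_fd(W, f, x, p)
    expect_equal(dW, -p$eta / (p$g * p$beta0 * p$phi0) * grad,
                 tolerance = 1e-5)
  }
})

test_that("signed rules share the joint error with opposite signs and
           truncate", {
  p <- default_p
  net <- tiny_net("signed", seed = 8)
  w <- net$weights
  y <- runif(10, 0, 1)
  x <- runif(8, 0, 1)
  v <- membrane_potential(w, x, y)$v
  # exact joint prediction freezes both M matrices
  f_fix <- static_sigmoid(v$M, p)
  w_fix <- update_signed(w, f_fix, x, y, params = p, plastic = "M")
  expect_equal(w_fix$M_exc, w$M_exc)
  expect_equal(w_fix$M_inh, w$M_inh)
  # positive error moves M_exc up and M_inh down where the trace is active
  f_hi <- pmin(static_sigmoid(v$M, p) + 20, 50)
  w_hi <- update_signed(w, f_hi, x, y, params = p, plastic = "M")
  d_exc <- (w_hi$M_exc - w$M_exc)[w$mask_exc == 1]
  d_inh <- (w_hi$M_inh - w$M_inh)[w$mask_inh == 1 & w$M_inh > 0]
  expect_true(all(d_exc >= 0) && any(d_exc > 0))
  expect_true(all(d_inh <= 0) && any(d_inh < 0))
  # truncation safety under aggressive depression
  w_lo <- update_signed(w, rep(0, 10), x, rep(1, 10), eta = 10, params = p)
  expect_gte(min(w_lo$M_exc), 0)
  expect_gte(min(w_lo$M_inh), 0)
  expect_gte(min(w_lo$G), 0)
})

test_that("DL rules split the two inhibitory paths correctly", {
  p <- default_p
  net <- tiny_net("DL", N = 6, K = 5, seed = 13)
  w <- net$weights
  x <- runif(5)
  y <- list(E = runif(6), I = numeric(6))
  # silent inhibitory pool freezes both G paths
  f <- list(E = rep(30, 6), I = rep(30, 6))
  w1 <- update_DL(w, f, x, y, params = p)
  for (nm in c("G1_EI", "G2_EI", "G1_II", "G2_II"))
    expect_equal(w1[[nm]], w[[nm]])
  expect_false(isTRUE(all.equal(w1$M_EE, w$M_EE)))

  # exact path-2 prediction freezes M_XE and G2 while G1 still moves
  y2 <- list(E = runif(6), I = runif(6))
  w$M_EE <- matrix(1, 6, 6)   # put the path-2 prediction mid-range
  w$M_IE <- matrix(1, 6, 6)
  v <- membrane_potential(w, x, y2)$v
  f2 <- list(E = static_sigmoid(v$E$M2, p), I = static_sigmoid(v$I$M2, p))
  w2 <- update_DL(w, f2, x, y2, params = p, plastic = c("M", "G"))
  expect_equal(w2$M_EE, w$M_EE)
  expect_equal(w2$G2_EI, w$G2_EI)
  expect_false(isTRUE(all.equal(w2$G1_EI, w$G1_EI)))
  # truncation safety
  w3 <- update_DL(w, list(E = rep(0, 6), I = rep(0, 6)), x,
                  list(E = rep(1, 6), I = rep(1, 6)), eta = 10, params = p)
  for (nm in c("M_EE", "M_IE", "G1_EI", "G2_EI", "G1_II", "G2_II"))
    expect_gte(min(w3[[nm]]), 0)
})

test_that("gating schedule returns the enabled set per interval and
           rejects overlap", {
  cfg <- plasticity_config(schedule = list(
    list(t_start = 3e5, t_end = 3.2e5, enabled = character(0)),
    list(t_start = 3.2e5, t_end = 4e5, enabled = c("W", "M"))))
  expect_setequal(apply_gating(cfg, 1e5), c("W", "M", "G"))  # learning
  expect_length(apply_gating(cfg, 3.1e5), 0)                 # recovery
  expect_setequal(apply_gating(cfg, 3.5e5), c("W", "M"))
  expect_setequal(apply_gating(cfg, 5e5), c("W", "M", "G"))
  expect_error(plasticity_config(schedule = list(
    list(t_start = 0, t_end = 100, enabled = "W"),
    list(t_start = 50, t_end = 150, enabled = "M"))), "overlap")
  expect_error(plasticity_config(schedule = list(
    list(t_start = 10, t_end = 5, enabled = "W"))))
})
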