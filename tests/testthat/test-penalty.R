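test_that("closed-form h-likelihood scale matches brute-force maximization", {
  set.seed(11)
  for (i in 1:60) {
    v <- runif(1, 0.05, 3)
    theta <- runif(1, 0.2, 3)
    w <- runif(1, 0.1, 8)
    uhat <- solve_hl_scale(v, theta, w)
    opt <- optimize(h_joint, c(1e-10, uhat * 10 + 10),
                    v = v, theta = theta, w = w,
                    maximum = TRUE, tol = 1e-12)
    expect_lt(abs(opt$maximum - uhat), 1e-5 * (1 + uhat))
  }
})

test_that("h-likelihood stationarity residual vanishes at the closed-form root", {
  set.seed(12)
  n_cases <- 1000
  v <- runif(n_cases, 0.05, 3)
  theta <- runif(n_cases, 0.2, 3)
  w <- runif(n_cases, 0.05, 10)
  for (i in seq_len(n_cases)) {
    uhat <- solve_hl_scale(v[i], theta[i], w[i])
    expect_lt(abs(h_joint_deriv(uhat, v[i], theta[i], w[i])), 1e-8)
  }
})

test_that("hl scale special values: ridge, cusp, origin", {
  expect_equal(solve_hl_scale(1.7, 1, 0), 1)     # w = 0 recovers ridge
  expect_equal(solve_hl_scale(1, 1, 2), 1)       # w = 2: u = |v|/sqrt(theta)
  expect_equal(solve_hl_scale(2, 4, 2), 1)
  expect_equal(solve_hl_scale(0, 1, 30), 0)      # infinite weight at origin
  expect_error(solve_hl_scale(1, -1, 2), "theta")
})

test_that("penalty derivatives match their definitions", {
  lasso <- penalty_spec("LASSO", lambda = 0.3)
  expect_equal(penalty_derivative(lasso, 5), 0.3)
  expect_equal(penalty_derivative(lasso, -5), 0.3)

  scad <- penalty_spec("SCAD", lambda = 1, scad_a = 3.7)
  expect_equal(penalty_derivative(scad, 0.5), 1)    # |v| <= lambda branch
  expect_equal(penalty_derivative(scad, 10), 0)     # beyond a*lambda
  # numerical differentiation of the SCAD penalty itself
  scad_pen <- function(v, lam = 1, a = 3.7) {
    av <- abs(v)
    ifelse(av <= lam, lam * av,
      ifelse(av <= a * lam,
             -(av^2 - 2 * a * lam * av + lam^2) / (2 * (a - 1)),
             (a + 1) * lam^2 / 2))
  }
  for (v in c(0.2, 0.9, 1.5, 2.5, 3.5)) {
    num <- (scad_pen(v + 1e-6) - scad_pen(v - 1e-6)) / 2e-6
    expect_equal(penalty_derivative(scad, v), num, tolerance = 1e-5)
  }

  en <- penalty_spec("EN", lambda = 0.5, en_lambda2 = 0.2)
  expect_equal(penalty_derivative(en, 2), 0.5 + 2 * 0.2 * 2)
  ridge <- penalty_spec("RIDGE", lambda = 0.5)
  expect_equal(penalty_derivative(ridge, 2), 2 * 0.5 * 2)
  none <- penalty_spec("NONE")
  expect_equal(penalty_derivative(none, 2), 0)
})

test_that("iwls weights: perturbed magnitude keeps every entry finite", {
  lasso <- penalty_spec("LASSO", lambda = 1, delta = 1e-8)
  expect_equal(iwls_weights(lasso, 0), 1e4)        # 1/sqrt(delta)
  hl0 <- penalty_spec("HL", lambda = 1, theta = 1, w = 0)
  expect_equal(iwls_weights(hl0, 3), 1, tolerance = 1e-6)
  hl30 <- penalty_spec("HL", lambda = 1, theta = 1, w = 30)
  wts <- iwls_weights(hl30, c(0, 0.01, 0.5, 2, 100))
  expect_true(all(is.finite(wts) & wts > 0))
})

test_that("w = 0 gives constant (ridge) weights in v", {
  hl0 <- penalty_spec("HL", lambda = 2, theta = 0.7, w = 0)
  v <- seq(-5, 5, length.out = 101)
  wts <- iwls_weights(hl0, v)
  expect_lt(diff(range(wts)) / mean(wts), 1e-10)
})

test_that("w = 2 reproduces the LASSO derivative up to a constant factor", {
  theta <- 0.3
  hl2 <- penalty_spec("HL", lambda = 1.5, theta = theta, w = 2)
  lasso <- penalty_spec("LASSO", lambda = 1.5)
  v <- seq(0.01, 10, length.out = 200)
  ratio <- penalty_derivative(hl2, v) / penalty_derivative(lasso, v)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  expect_equal(mean(ratio), sqrt(theta), tolerance = 1e-10)
})

test_that("for w > 2 the HL weight is strictly decreasing in |v|", {
  hl <- penalty_spec("HL", lambda = 1, theta = 0.5, w = 30)
  v <- seq(0, 5, length.out = 200)
  wts <- iwls_weights(hl, v)
  expect_true(all(diff(wts) < 0))
})

test_that("tail behavior: HL and SCAD weights vanish, LASSO's does not", {
  big <- 50
  hl <- penalty_spec("HL", lambda = 1, theta = 1, w = 30)
  scad <- penalty_spec("SCAD", lambda = 1)
  lasso <- penalty_spec("LASSO", lambda = 1)
  expect_lt(iwls_weights(hl, big), 1e-1)
  expect_equal(iwls_weights(scad, big), 0)
  expect_equal(iwls_weights(lasso, big), 1 / sqrt(big^2 + 1e-8))
})

test_that("estimates are robust to the size of the delta perturbation", {
  fx <- make_support_fixture()
  Xc <- center_columns(fx$X)
  for (fam in c("HL", "LASSO")) {
    s8 <- penalty_spec(fam, lambda = 5, theta = 1 / 6, delta = 1e-8)
    s9 <- penalty_spec(fam, lambda = 5, theta = 1 / 6, delta = 1e-9)
    f8 <- sspca_fit(Xc, 1, s8)
    f9 <- sspca_fit(Xc, 1, s9)
    expect_lt(max(abs(f8$loadings - f9$loadings)), 1e-4)
  }
})

test_that("penalty_spec validates its parameters", {
  expect_error(penalty_spec("HL", theta = 0), "theta")
  expect_error(penalty_spec("SCAD", scad_a = 2), "scad_a")
  expect_error(penalty_spec("LASSO", lambda = -1), "lambda")
  expect_error(penalty_spec("XXX"))
})
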