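test_that("center_columns removes means and keeps labels", {
  M <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  cm <- center_columns(M)
  expect_equal(cm$values, matrix(c(-1, 1, -1, 1), 2, 2,
                                 dimnames = dimnames(M)))
  expect_equal(unname(cm$column_means), c(2, 3))
  expect_equal(cm$col_labels, c("g1", "g2"))
  # constant column becomes zero; centered input is unchanged
  M2 <- cbind(rep(5, 4), c(-1, 1, -2, 2))
  cm2 <- center_columns(M2)
  expect_equal(unname(cm2$values[, 1]), rep(0, 4))
  expect_equal(unname(cm2$values[, 2]), M2[, 2])
  expect_error(center_columns(cbind(c(1, NA), c(1, 2))), "non-finite")
  expect_error(center_columns(matrix(1, 1, 3)), "2 rows")
})

test_that("nipals recovers the leading singular triplet", {
  # diagonal matrix: exact
  f <- nipals_first_component(diag(c(3, 1)))
  expect_equal(f$v, c(1, 0))
  expect_equal(f$d, 3)
  # rank-1: fixed point in one sweep
  u <- c(1, 2, -1, 3); w <- c(2, -1, 0.5)
  f1 <- nipals_first_component(tcrossprod(u, w))
  expect_equal(abs(sum(f1$v * w / sqrt(sum(w^2)))), 1, tolerance = 1e-12)
  # random matrix vs dense SVD oracle
  set.seed(21)
  X <- scale(matrix(rnorm(20 * 5), 20, 5), scale = FALSE)
  f2 <- nipals_first_component(X)
  s <- svd(X)
  expect_gt(abs(sum(f2$v * s$v[, 1])), 1 - 1e-10)
  expect_equal(f2$d, s$d[1], tolerance = 1e-8)
  expect_error(nipals_first_component(matrix(0, 3, 3)), "zero")
})

test_that("sparse loading step reduces to OLS without penalty and to 0 at huge lambda", {
  set.seed(22)
  X <- scale(matrix(rnorm(40 * 8), 40, 8), scale = FALSE)
  z <- X[, 1]
  ols <- drop(crossprod(X, z)) / sum(z^2)
  s0 <- sparse_loading_step(X, z, penalty_spec("NONE"))
  expect_equal(s0$v, ols)
  shuge <- sparse_loading_step(X, z, penalty_spec("LASSO", lambda = 1e12))
  expect_lt(max(abs(shuge$v)), 1e-6)
})

test_that("sparse loading step recovers a strong-signal support", {
  fx <- make_support_fixture()
  Xc <- center_columns(fx$X)$values
  # exhaustive oracle: best 2-variable OLS fit of the columns on z
  rss <- function(idx) {
    v <- rep(0, ncol(Xc))
    v[idx] <- drop(crossprod(Xc[, idx], fx$z)) / sum(fx$z^2)
    sum((Xc - tcrossprod(fx$z, v))^2)
  }
  pairs <- combn(ncol(Xc), 2)
  best <- pairs[, which.min(apply(pairs, 2, rss))]
  expect_equal(sort(best), fx$support)
  st <- sparse_loading_step(Xc, fx$z,
                            penalty_spec("HL", lambda = 20, theta = 1 / 6,
                                         w = 30))
  expect_equal(sort(which(abs(st$v) >= 5e-5)), fx$support)
})

test_that("penalty-free fit reproduces dense SVD on tall and wide matrices", {
  for (dims in list(c(80, 20), c(50, 200))) {
    set.seed(sum(dims))
    X <- scale(matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2]),
               scale = FALSE)
    k <- 4
    fit <- sspca_fit(X, k = k, spec = penalty_spec("NONE"))
    s <- svd(X)
    for (j in seq_len(k)) {
      expect_gt(abs(sum(fit$loadings[, j] * s$v[, j])), 1 - 1e-8)
      expect_equal(fit$singular_values[j], s$d[j], tolerance = 1e-8)
    }
    expect_true(all(diff(fit$singular_values) <= 1e-8))
    # variances: adjusted variance equals d^2 / (n * total)
    expect_equal(fit$adjusted_variance,
                 100 * s$d[1:k]^2 / sum(s$d^2), tolerance = 1e-8)
  }
})

test_that("fits are deterministic and satisfy bookkeeping invariants", {
  set.seed(23)
  X <- scale(matrix(rnorm(60 * 10), 60, 10), scale = FALSE)
  spec <- penalty_spec("HL", lambda = 8, theta = 0.1, w = 30)
  f1 <- sspca_fit(X, k = 3, spec = spec)
  f2 <- sspca_fit(X, k = 3, spec = spec)
  expect_identical(f1$loadings, f2$loadings)
  # unit norms, sign canonicalization, nonzero counts
  for (j in 1:3) {
    v <- f1$loadings[, j]
    expect_equal(sum(v^2), 1, tolerance = 1e-8)
    expect_gt(v[which.max(abs(v))], 0)
    expect_equal(f1$nonzero_counts[[j]], sum(abs(v) >= 5e-5))
  }
  # deflation removes each extracted direction
  Xd <- X
  for (j in 1:3) {
    Xd <- Xd - tcrossprod(f1$scores[, j], f1$loadings[, j])
    expect_lt(sqrt(sum((Xd %*% f1$loadings[, j])^2)), 1e-6 * f1$singular_values[1])
  }
  expect_error(sspca_fit(X, k = 11, spec = spec), "k must be")
})

test_that("nonzero counts are non-increasing in lambda (HL, fixed theta)", {
  fx <- make_support_fixture(n = 40, p = 10, seed = 7)
  Xc <- center_columns(fx$X)
  counts <- vapply(c(0.1, 1, 5, 25, 125, 600), function(lam) {
    f <- sspca_fit(Xc, 1, penalty_spec("HL", lambda = lam, theta = 0.1,
                                       w = 30))
    f$nonzero_counts[[1]]
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("single-factor data: penalized first loading finds the signal block", {
  sc <- sim_scenario(80, 20, beta_sq = 2)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    dat <- sim_generate(sc)
    Xc <- center_columns(dat$X)
    f <- sspca_fit(Xc, 1, penalty_spec("HL", lambda = 30, theta = 1 / 20,
                                       w = 30))
    nz <- which(abs(f$loadings[, 1]) >= 5e-5)
    if (all(nz %in% dat$support)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
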