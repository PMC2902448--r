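# Tuning of the random-effect penalty: moment estimator for the
# dispersion theta, K-fold cross-validation for lambda.

#' Tuning configuration
#'
#' @param K Fold count for cross-validation (default 5).
#' @param lambda_grid Strictly increasing positive candidate values,
#'   or `NULL` to build a default data-driven grid at fit time
#'   ([default_lambda_grid()]).
#' @param seed Optional integer seed making the fold assignment
#'   reproducible.
#' @param theta_override Optional fixed dispersion, bypassing
#'   [estimate_theta()].
#' @return An object of class `"tuning_config"`.
#' @export
tuning_config <- function(K = 5L, lambda_grid = NULL, seed = NULL,
                          theta_override = NULL) {
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (!is.null(lambda_grid)) {
    if (length(lambda_grid) == 0 || any(lambda_grid <= 0) ||
        is.unsorted(lambda_grid, strictly = TRUE))
      stop("lambda_grid must be positive and strictly increasing",
           call. = FALSE)
  }
  if (!is.null(theta_override) && theta_override <= 0)
    stop("theta_override must be positive", call. = FALSE)
  structure(list(K = as.integer(K), lambda_grid = lambda_grid,
                 seed = seed, theta_override = theta_override),
            class = "tuning_config")
}

#' Moment estimate of the loading dispersion
#'
#' Under the random-effect model the loadings have marginal mean zero
#' and variance \eqn{\theta}; the estimator is the raw second moment of
#' the ordinary-PCA first loading, \eqn{\hat\theta = p^{-1}\sum_j
#' \hat v_{1j}^2}.  (Because the loading has unit norm this equals
#' \eqn{1/p}; the computation is kept explicit so that the estimator
#' tracks whatever loading normalization is in force.)
#'
#' @param X `centered_matrix` or numeric matrix.
#' @return Positive scalar \eqn{\hat\theta}.
#' @export
estimate_theta <- function(X) {
  Xv <- as_values(X)
  if (all(Xv == 0)) stop("matrix is identically zero", call. = FALSE)
  v1 <- nipals_first_component(Xv)$v
  mean(v1^2)
}

#' Default lambda grid
#'
#' 20 log-spaced points spanning `[1e-4, 1e2]` times a data-driven
#' scale, the median of `|X'z|` at the leading NIPALS score `z`.  On
#' that scale the weighted ridge term competes with `z'z`, so the grid
#' brackets both the no-shrinkage and the all-zero regimes.
#'
#' @param X `centered_matrix` or numeric matrix.
#' @param n_points Grid size (default 20).
#' @return Increasing vector of positive lambdas.
#' @export
default_lambda_grid <- function(X, n_points = 20L) {
  Xv <- as_values(X)
  z <- nipals_first_component(Xv)$z
  scale <- stats::median(abs(drop(crossprod(Xv, z))))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  exp(seq(log(1e-4), log(1e2), length.out = n_points)) * scale
}

#' Select lambda by K-fold cross-validation of the test variance
#'
#' For each candidate lambda and each fold, the first sparse loading is
#' fitted on the training rows (centered by training means) and scored
#' by the variance it captures on the held-out rows,
#' \eqn{\hat v' S_{X[k]} \hat v} with the validation rows centered by
#' the training means.  Fold scores are summed and the arg-max lambda
#' returned, ties broken toward the larger (sparser) value.
#'
#' @param X `centered_matrix` or numeric matrix.
#' @param spec_template A [penalty_spec()] supplying family, `theta`,
#'   `w`, etc.; its `lambda` is overwritten by each candidate.
#' @param cfg A [tuning_config()].
#' @return The selected lambda (scalar).
#' @export
select_lambda_cv <- function(X, spec_template, cfg = tuning_config()) {
  Xv <- as_values(X)
  n <- nrow(Xv)
  if (n < cfg$K) stop("fewer rows than folds", call. = FALSE)
  grid <- if (is.null(cfg$lambda_grid)) default_lambda_grid(Xv)
          else cfg$lambda_grid
  if (length(grid) == 1L) return(grid)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fold_id <- sample(rep_len(seq_len(cfg$K), n))
  score <- rep(0, length(grid))
  for (fk in seq_len(cfg$K)) {
    tr <- Xv[fold_id != fk, , drop = FALSE]
    va <- Xv[fold_id == fk, , drop = FALSE]
    mu <- colMeans(tr)
    tr_c <- sweep(tr, 2, mu)
    va_c <- sweep(va, 2, mu)
    S_va <- crossprod(va_c) / nrow(va_c)
    for (gi in seq_along(grid)) {
      spec_g <- spec_template
      spec_g$lambda <- grid[gi]
      fit <- tryCatch(
        penalized_first_component(tr_c, spec_g),
        error = function(e) NULL)
      score[gi] <- score[gi] + if (is.null(fit) || all(fit$v == 0)) -Inf
        else drop(crossprod(fit$v, S_va %*% fit$v))
    }
  }
  best <- max(score)
  grid[max(which(score >= best - 1e-12 * max(abs(best), 1)))]
}
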