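# NIPALS power iteration and its penalized modification.
#
# Ordinary NIPALS extracts one singular pair at a time by alternating
# the regressions v <- X'z / z'z and z <- Xv.  The sparse variants
# replace the v-step by a penalized (IWLS) regression; the condition
# -number-shrunken matrix X* may stand in for X during loading
# estimation (see shrink_matrix), while scores and deflation always use
# the data itself.

#' Center the columns of a data matrix
#'
#' Removes column means and stores them, returning a `centered_matrix`
#' object (values, removed means, row/column labels).  All analysis
#' functions in the package accept either this object or a plain
#' numeric matrix that is assumed to be already processed.
#'
#' @param raw Numeric matrix, rows = samples, columns = variables.
#' @return An object of class `"centered_matrix"` with elements
#'   `values`, `column_means`, `row_labels`, `col_labels`.
#' @examples
#' cm <- center_columns(matrix(c(1, 3, 2, 4), 2, 2))
#' cm$values
#' @export
center_columns <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("input matrix must be numeric", call. = FALSE)
  if (any(!is.finite(raw)))
    stop("input matrix contains non-finite entries", call. = FALSE)
  if (nrow(raw) < 2) stop("need at least 2 rows (samples)", call. = FALSE)
  mu <- colMeans(raw)
  structure(
    list(values = sweep(raw, 2, mu),
         column_means = mu,
         row_labels = rownames(raw),
         col_labels = colnames(raw)),
    class = "centered_matrix")
}

#' @export
print.centered_matrix <- function(x, ...) {
  cat("Centered matrix:", nrow(x$values), "samples x",
      ncol(x$values), "variables\n")
  invisible(x)
}

# Accept centered_matrix or plain matrix everywhere.
as_values <- function(X) {
  if (inherits(X, "centered_matrix")) X$values else as.matrix(X)
}

# Initial score: first column of X, falling back to the column of
# largest norm if the first is numerically zero.
nipals_init_score <- function(X) {
  z <- X[, 1L]
  if (sqrt(sum(z^2)) <= 1e-12 * sqrt(sum(X^2))) {
    j <- which.max(colSums(X^2))
    z <- X[, j]
  }
  z
}

# Deterministic sign: largest-magnitude entry of v made positive.
canonical_sign <- function(v) {
  j <- which.max(abs(v))
  if (v[j] < 0) -v else v
}

#' Leading principal component by NIPALS
#'
#' Power-method-style extraction of the leading singular triplet.
#' Starting from `z` = first column of `X`, iterates
#' `v <- X'z / z'z`, normalize `v`, `z <- X v` until the change in `v`
#' drops below `tol`.
#'
#' @param X `centered_matrix` or numeric matrix.
#' @param tol Convergence tolerance on the max-norm change of `v`.  The
#'   default is tight (1e-9) because the unpenalized power iteration
#'   converges linearly and the extra sweeps are cheap; the penalized
#'   driver uses a looser 1e-6.
#' @param max_iter Iteration cap; non-convergence is flagged, the best
#'   iterate returned.
#' @return List with `v` (unit loading), `z` (scores `X v`),
#'   `d` (`||X v||`), `iterations`, `converged`.
#' @export
nipals_first_component <- function(X, tol = 1e-9, max_iter = 1000L) {
  X <- as_values(X)
  if (all(X == 0)) stop("matrix is identically zero", call. = FALSE)
  z <- nipals_init_score(X)
  v_old <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    v <- drop(crossprod(X, z)) / sum(z^2)
    v <- v / sqrt(sum(v^2))
    v <- canonical_sign(v)
    z <- drop(X %*% v)
    if (max(abs(v - v_old)) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    v_old <- v
  }
  if (!converged)
    warning("NIPALS did not converge in ", max_iter, " iterations",
            call. = FALSE)
  list(v = v, z = z, d = sqrt(sum(z^2)), iterations = it,
       converged = converged)
}

#' Penalized loading step (inner IWLS)
#'
#' Given a score vector `z`, solves the column-wise penalized
#' regression of each `X_j` on `z`:
#' \deqn{v_j = (z'z + W_j)^{-1} X_j' z,}
#' where `W_j` is the diagonal IWLS weight [iwls_weights()] refreshed at
#' the current `v`, iterated to convergence.  With `family = "NONE"`
#' (zero weights) this is the OLS step of ordinary NIPALS.  The
#' returned vector is \emph{not} normalized; the NIPALS driver applies
#' the unit-norm constraint inside its own loop.
#'
#' @param X `centered_matrix` or matrix (possibly the shrunken `X*`).
#' @param z Nonzero score vector, length `nrow(X)`.
#' @param spec A [penalty_spec()].
#' @param v_init Optional warm start; defaults to the OLS solution.
#' @param tol,max_iter Inner IWLS convergence controls.
#' @return List with `v`, `iterations`, `converged`.
#' @export
sparse_loading_step <- function(X, z, spec, v_init = NULL,
                                tol = 1e-6, max_iter = 100L) {
  X <- as_values(X)
  ztz <- sum(z^2)
  if (ztz <= 0) stop("score vector z is zero", call. = FALSE)
  xtz <- drop(crossprod(X, z))
  if (spec$family == "NONE" || spec$lambda == 0)
    return(list(v = xtz / ztz, iterations = 1L, converged = TRUE))
  v <- if (is.null(v_init)) xtz / ztz else v_init
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wts <- iwls_weights(spec, v)
    v_new <- xtz / (ztz + wts)
    if (max(abs(v_new - v)) < tol) { v <- v_new; converged <- TRUE; break }
    v <- v_new
  }
  list(v = v, iterations = it, converged = converged)
}

# One penalized NIPALS component on the working matrix X (already
# shrunken if requested).  Normalization is applied inside the loop.
penalized_first_component <- function(X, spec, tol = 1e-6,
                                      max_iter = 500L,
                                      inner_tol = 1e-6,
                                      inner_max_iter = 100L) {
  z <- nipals_init_score(X)
  v_old <- rep(0, ncol(X))
  v <- NULL
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    step <- sparse_loading_step(X, z, spec, v_init = v,
                                tol = inner_tol,
                                max_iter = inner_max_iter)
    v <- step$v
    nv <- sqrt(sum(v^2))
    if (nv == 0) {
      # total shrinkage: return the zero direction, flagged converged
      v <- rep(0, ncol(X))
      converged <- TRUE
      break
    }
    v <- canonical_sign(v / nv)
    z <- drop(X %*% v)
    if (max(abs(v - v_old)) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    v_old <- v
  }
  list(v = v, iterations = it, converged = converged)
}

#' Fit sparse (or ordinary) principal components
#'
#' Multi-component driver.  For each component the working matrix is
#' optionally replaced by its condition-number-shrunken version `X*`
#' ([shrink_matrix()]) for loading estimation; the modified NIPALS loop
#' is run with the requested penalty; scores, singular values and the
#' deflation `X <- X - z v'` are computed on the \emph{unshrunken}
#' current matrix so that variances refer to the data.  `X*` is
#' recomputed from the deflated matrix for each subsequent component.
#'
#' Tuning: if `spec$lambda` is `NA`, `theta` is set to the moment
#' estimate [estimate_theta()] (unless `tuning$theta_override` is
#' given) and `lambda` is chosen per component by K-fold
#' cross-validation [select_lambda_cv()] on the (shrunken, deflated)
#' working matrix.
#'
#' @param X `centered_matrix` or numeric matrix (columns centered).
#' @param k Number of components, `1 <= k <= min(n, p)`.
#' @param spec A [penalty_spec()]; use family `"NONE"` for ordinary
#'   PCA.  `lambda = NA` requests cross-validated tuning.
#' @param shrink Logical: apply condition-number shrinkage before each
#'   loading estimation (the "super-sparse" variant)?
#' @param kappa_max Condition-number bound; `NULL` selects it once on
#'   the full matrix by [select_kappa_cv()].
#' @param tuning A [tuning_config()].
#' @param tol,max_iter Outer NIPALS controls; `tol = NULL` (default)
#'   uses 1e-9 for the unpenalized power iteration and 1e-6 for the
#'   penalized loop.
#' @return An object of class `"sspca_fit"`: `loadings` (p x k),
#'   `scores` (n x k), `singular_values`, `nonzero_counts`,
#'   `adjusted_variance` and `cumulative_adjusted_variance` (percent),
#'   `penalty`, `lambdas`, `theta`, `kappa_max`, `converged_flags`,
#'   `iteration_counts`.
#' @examples
#' X <- center_columns(matrix(rnorm(200), 20, 10))
#' fit <- sspca_fit(X, k = 2, spec = penalty_spec("NONE"))
#' fit$singular_values
#' @export
sspca_fit <- function(X, k = 1L, spec = penalty_spec("NONE"),
                      shrink = FALSE, kappa_max = NULL,
                      tuning = tuning_config(),
                      tol = NULL, max_iter = 500L) {
  Xc <- as_values(X)
  n <- nrow(Xc); p <- ncol(Xc)
  if (k < 1 || k > min(n, p))
    stop("k must be between 1 and min(n, p)", call. = FALSE)
  r <- qr(Xc)$rank
  if (k > r) stop("k exceeds the rank of the matrix", call. = FALSE)

  if (shrink && is.null(kappa_max))
    kappa_max <- select_kappa_cv(Xc, folds = tuning$K, seed = tuning$seed)

  loadings <- matrix(0, p, k)
  scores <- matrix(0, n, k)
  d <- numeric(k)
  lambdas <- numeric(k)
  iters <- integer(k)
  conv <- logical(k)
  theta_used <- NA_real_

  Xcur <- Xc
  for (j in seq_len(k)) {
    Xwork <- if (shrink) shrink_matrix(Xcur, kappa_max)$X_star else Xcur
    spec_j <- spec
    if (spec$family != "NONE") {
      if (is.na(spec$lambda)) {
        theta_used <- if (!is.null(tuning$theta_override))
          tuning$theta_override else estimate_theta(Xwork)
        spec_j$theta <- theta_used
        spec_j$lambda <- select_lambda_cv(Xwork, spec_j, tuning)
      } else {
        theta_used <- spec$theta
      }
    }
    lambdas[j] <- spec_j$lambda
    comp <- if (spec_j$family == "NONE")
      nipals_first_component(Xwork, tol = if (is.null(tol)) 1e-9 else tol,
                             max_iter = max(max_iter, 1000L))
    else
      penalized_first_component(Xwork, spec_j,
                                tol = if (is.null(tol)) 1e-6 else tol,
                                max_iter = max_iter)
    v <- comp$v
    z <- drop(Xcur %*% v)
    loadings[, j] <- v
    scores[, j] <- z
    d[j] <- sqrt(sum(z^2))
    iters[j] <- comp$iterations
    conv[j] <- comp$converged
    Xcur <- Xcur - tcrossprod(z, v)
  }

  av <- adjusted_variance(Xc, loadings)
  labs <- if (inherits(X, "centered_matrix")) X$col_labels else colnames(Xc)
  if (!is.null(labs)) rownames(loadings) <- labs
  structure(
    list(loadings = loadings, scores = scores, singular_values = d,
         nonzero_counts = colSums(abs(loadings) >= spec$zero_threshold),
         penalty = spec, lambdas = lambdas, theta = theta_used,
         kappa_max = if (shrink) kappa_max else NA_real_,
         shrink = shrink,
         adjusted_variance = av$adjusted,
         cumulative_adjusted_variance = av$cumulative,
         converged_flags = conv, iteration_counts = iters,
         n = n, p = p),
    class = "sspca_fit")
}

#' @export
print.sspca_fit <- function(x, ...) {
  meth <- if (x$penalty$family == "NONE") "PCA"
          else if (x$shrink) paste0("SSPCA-", x$penalty$family)
          else paste0("SPCA-", x$penalty$family)
  cat(meth, "fit:", x$n, "samples x", x$p, "variables,",
      length(x$singular_values), "component(s)\n")
  tab <- data.frame(
    d = round(x$singular_values, 4),
    nonzero = x$nonzero_counts,
    lambda = signif(x$lambdas, 4),
    adj_var_pct = round(x$adjusted_variance, 2),
    cum_adj_var_pct = round(x$cumulative_adjusted_variance, 2))
  print(tab)
  if (x$shrink) cat("kappa_max =", format(x$kappa_max), "\n")
  invisible(x)
}
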