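# Number of significant components (row-wise permutation test) and
# adjusted-variance accounting for correlated sparse scores.

#' Permutation test for the number of significant components
#'
#' Each permutation independently shuffles the expression values
#' within every sample (row) of `X`, destroying between-variable
#' correlation while preserving each row's value set.  The singular
#' values of the re-centered permuted matrices form the null; the
#' p-value of the observed \eqn{d_k} is
#' \eqn{(1 + \#\{d_k^{perm} \ge d_k\})/(P + 1)} (add-one corrected,
#' never exactly zero, compared per rank \eqn{k}).  The selected count
#' `k0` is the largest `k` such that all p-values up to `k` fall below
#' `alpha`.
#'
#' @param X `centered_matrix` or numeric matrix.
#' @param P Number of permutations (>= 1; 1000 in typical use, so the
#'   smallest attainable p-value 1/1001 can clear `alpha = 0.001`).
#' @param alpha Significance threshold in (0, 1).
#' @param seed Optional integer seed.
#' @return An object of class `"permutation_result"`: `d_observed`,
#'   `perm_null` (P x k matrix), `p_values`, `k0`, `P`, `alpha`.
#' @export
permutation_component_count <- function(X, P = 1000L, alpha = 0.001,
                                        seed = NULL) {
  Xv <- as_values(X)
  if (P < 1) stop("P must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Xv); p <- ncol(Xv)
  k <- min(n, p)
  d_obs <- svd(scale(Xv, center = TRUE, scale = FALSE),
               nu = 0, nv = 0)$d
  perm_null <- matrix(0, P, k)
  for (b in seq_len(P)) {
    Xp <- t(apply(Xv, 1, sample))
    Xp <- scale(Xp, center = TRUE, scale = FALSE)
    perm_null[b, ] <- svd(Xp, nu = 0, nv = 0)$d
  }
  p_values <- vapply(seq_len(k), function(j)
    (1 + sum(perm_null[, j] >= d_obs[j])) / (P + 1), numeric(1))
  below <- p_values < alpha
  k0 <- if (below[1]) max(which(cumsum(!below) == 0)) else 0L
  structure(
    list(d_observed = d_obs, perm_null = perm_null,
         p_values = p_values, k0 = as.integer(k0),
         P = as.integer(P), alpha = alpha),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (P =", x$P, ", alpha =", x$alpha, "):",
      x$k0, "significant component(s)\n")
  k_show <- min(length(x$p_values), max(x$k0 + 2L, 5L))
  tab <- data.frame(d = round(x$d_observed[seq_len(k_show)], 4),
                    p_value = signif(x$p_values[seq_len(k_show)], 3))
  print(tab)
  invisible(x)
}

#' Adjusted explained variance for (possibly correlated) components
#'
#' Sparse loadings are generally non-orthogonal, so their scores are
#' correlated and naive per-component variances double-count.  The
#' adjusted variance of component `k` is the squared `k`-th diagonal
#' entry of the triangular factor of the QR decomposition of the score
#' matrix `Z = X L`, divided by `n`, expressed as a percent of the
#' total variance `tr(S_X)`.  For orthogonal ordinary-PCA scores this
#' reduces to the usual explained variance.
#'
#' @param X `centered_matrix` or numeric matrix.
#' @param loadings p x k matrix of unit-norm loading columns.
#' @return List with `adjusted` and `cumulative` (percent vectors of
#'   length k).
#' @export
adjusted_variance <- function(X, loadings) {
  Xv <- as_values(X)
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != ncol(Xv))
    stop("loadings must have one row per variable", call. = FALSE)
  n <- nrow(Xv)
  total <- sum(Xv^2) / n
  Z <- Xv %*% loadings
  R <- qr.R(qr(Z))
  adj <- diag(R)^2 / n
  # QR of a rank-deficient Z can leave numerical dust on the diagonal
  adj[adj < 1e-12 * max(adj, 0)] <- 0
  adj_pct <- 100 * adj / total
  list(adjusted = adj_pct, cumulative = cumsum(adj_pct))
}
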