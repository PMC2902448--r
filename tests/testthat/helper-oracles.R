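# Independent oracles used across test files.

# Log joint density of the random-effect hierarchy evaluated directly:
# v | u ~ N(0, u * theta), u ~ Gamma(shape 1/w, scale w) (mean 1,
# variance w); the second term is the density of log(u), hence + log(u).
h_joint <- function(u, v, theta, w) {
  stats::dnorm(v, 0, sqrt(u * theta), log = TRUE) +
    stats::dgamma(u, shape = 1 / w, scale = w, log = TRUE) +
    log(u)
}

# Analytic derivative of h_joint in u, derived term by term from the
# densities above (independently of the closed-form root).
h_joint_deriv <- function(u, v, theta, w) {
  v^2 / (2 * theta * u^2) + (1 / w - 1 / 2) / u - 1 / w
}

# Brute-force maximizer of the profiled constrained spectrum
# likelihood over a dense grid of t (oracle for truncate_spectrum).
brute_force_truncate <- function(l, kappa_max, n_grid = 200000L) {
  obj <- function(t) {
    u <- pmin(pmax(1 / l, t), kappa_max * t)
    sum(log(u) - l * u)
  }
  tg <- exp(seq(log(1 / (kappa_max * l[1])) - 0.5,
                log(1 / l[length(l)]) + 0.5, length.out = n_grid))
  vals <- vapply(tg, obj, numeric(1))
  t_star <- tg[which.max(vals)]
  list(t_star = t_star,
       l_star = 1 / pmin(pmax(1 / l, t_star), kappa_max * t_star))
}

# Small strong-signal regression fixture: two true nonzero loadings.
make_support_fixture <- function(n = 30, p = 6, seed = 42) {
  set.seed(seed)
  z <- rnorm(n, sd = 3)
  v_true <- c(0.8, 0.6, rep(0, p - 2))
  X <- tcrossprod(z, v_true) + matrix(rnorm(n * p, sd = 0.05), n, p)
  list(X = X, z = z, v_true = v_true, support = 1:2)
}
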