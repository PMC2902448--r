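# Penalty families for the sparse NIPALS regression step.
#
# The sparse loading step minimizes, column by column,
#   ||X_j - v_j z||^2 + p_lambda(|v_j|),
# and the IWLS linearization replaces the penalty by the quadratic
# p'_lambda(|v_j|)/|v_j| * v_j^2 / 2, so everything downstream only needs
# the derivative p'_lambda(|v|) and the ratio p'_lambda(|v|)/|v|.

#' Penalty specification for sparse loading estimation
#'
#' Bundles a penalty family and its parameters.  The `HL` family is the
#' gamma random-effect (h-likelihood) penalty: the loading is modelled
#' hierarchically as \eqn{v | u \sim N(0, u\theta)} with
#' \eqn{u \sim \mathrm{Gamma}} scaled so that \eqn{E(u) = 1} and
#' \eqn{\mathrm{Var}(u) = w}.  Profiling \eqn{u} out of the h-likelihood
#' yields a penalty that is quadratic (ridge) at \eqn{w = 0}, has a
#' LASSO-like cusp at \eqn{w = 2}, and is unbounded at the origin for
#' \eqn{w > 2}; `w = 30` is the default super-sparse choice.
#'
#' @param family One of `"HL"`, `"LASSO"`, `"SCAD"`, `"EN"`, `"RIDGE"`,
#'   `"NONE"`.
#' @param lambda Non-negative penalty strength, or `NA` to request
#'   cross-validated selection at fit time.  For `HL` this is the ratio
#'   \eqn{\lambda = \phi/\theta}; the scale \eqn{\phi} is never needed
#'   separately.
#' @param theta Positive dispersion of the loading prior (`HL` only).
#' @param w Non-negative variance of the gamma scale mixture (`HL`
#'   only).  `w = 0` reproduces ridge, `w = 2` LASSO-like behaviour.
#' @param delta Small positive perturbation: IWLS weights are evaluated
#'   at \eqn{\tilde v = \sqrt{v^2 + \delta}} so they stay finite at
#'   \eqn{v = 0}.
#' @param scad_a SCAD shape parameter (> 2); 3.7 is the standard choice.
#' @param en_lambda2 Ridge part of the elastic-net penalty
#'   \eqn{\lambda |v| + \lambda_2 v^2}.
#' @param zero_threshold Reporting threshold: loadings with absolute
#'   value below it are reported as zero (default 5e-5).  Stored
#'   loadings are never truncated.
#' @return An object of class `"penalty_spec"`.
#' @examples
#' penalty_spec("HL", lambda = 10, theta = 0.05)
#' penalty_spec("LASSO", lambda = 1)
#' @export
penalty_spec <- function(family = c("HL", "LASSO", "SCAD", "EN", "RIDGE", "NONE"),
                         lambda = 0, theta = 1, w = 30, delta = 1e-8,
                         scad_a = 3.7, en_lambda2 = 0,
                         zero_threshold = 5e-5) {
  family <- match.arg(toupper(family[1]),
                      c("HL", "LASSO", "SCAD", "EN", "RIDGE", "NONE"))
  # lambda = NA requests cross-validated selection at fit time
  if (length(lambda) == 1L && is.na(lambda)) lambda <- NA_real_
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (!is.na(lambda) && (!is.finite(lambda) || lambda < 0))
    stop("`lambda` must be non-negative (or NA for CV tuning)",
         call. = FALSE)
  if (!(is.numeric(theta) && length(theta) == 1L && is.finite(theta) &&
        theta > 0))
    stop("`theta` must be a positive number", call. = FALSE)
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w), w >= 0)
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  if (scad_a <= 2) stop("`scad_a` must exceed 2", call. = FALSE)
  stopifnot(en_lambda2 >= 0, zero_threshold > 0)
  structure(
    list(family = family, lambda = lambda, theta = theta, w = w,
         delta = delta, scad_a = scad_a, en_lambda2 = en_lambda2,
         zero_threshold = zero_threshold),
    class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat("Penalty spec:", x$family, "\n")
  cat("  lambda =", format(x$lambda), " theta =", format(x$theta),
      " w =", format(x$w), "\n")
  if (x$family == "SCAD") cat("  scad_a =", x$scad_a, "\n")
  if (x$family == "EN") cat("  en_lambda2 =", x$en_lambda2, "\n")
  cat("  delta =", format(x$delta),
      " zero_threshold =", format(x$zero_threshold), "\n")
  invisible(x)
}

#' Profile h-likelihood scale estimate
#'
#' Solves the stationarity equation \eqn{dh/du = 0} of the h-likelihood
#' for the gamma scale \eqn{u} at a fixed loading value \eqn{v}.  With
#' \eqn{v|u \sim N(0, u\theta)} and \eqn{u \sim \mathrm{Gamma}} (mean 1,
#' variance \eqn{w}), the stationary point solves
#' \deqn{\hat u^2 + \hat u (w/2 - 1) - w v^2 / (2\theta) = 0,}
#' whose non-negative root is returned:
#' \deqn{\hat u = \{ (1 - w/2) + \sqrt{(w/2-1)^2 + 2 w v^2/\theta} \} / 2.}
#' At \eqn{w = 0} the mixture degenerates and \eqn{\hat u = 1} (ridge);
#' at \eqn{w = 2}, \eqn{\hat u = |v|/\sqrt\theta}; for \eqn{w > 2},
#' \eqn{\hat u \to 0} as \eqn{v \to 0}, so the implied IWLS weight
#' diverges at the origin — the source of super-sparsity.
#'
#' @param v Loading value(s); vectorized.
#' @param theta Positive dispersion.
#' @param w Non-negative gamma variance.
#' @return \eqn{\hat u \ge 0}, same length as `v`.
#' @export
solve_hl_scale <- function(v, theta, w) {
  if (!(is.numeric(theta) && length(theta) == 1L && is.finite(theta) &&
        theta > 0))
    stop("`theta` must be a positive number", call. = FALSE)
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0)
  b <- w / 2 - 1
  (-b + sqrt(b^2 + 2 * w * v^2 / theta)) / 2
}

#' Penalty derivative
#'
#' The derivative \eqn{p'_\lambda(|v|)} of the penalty with respect to
#' the loading magnitude.
#'
#' Families: LASSO gives \eqn{\lambda}; SCAD gives
#' \eqn{\lambda\{I(|v|\le\lambda) + (a\lambda-|v|)_+ /((a-1)\lambda)
#' I(|v|>\lambda)\}}; HL gives \eqn{\lambda |v| / \hat u(|v|)} with
#' \eqn{\hat u} from [solve_hl_scale()]; elastic net gives
#' \eqn{\lambda + 2\lambda_2 |v|}; ridge uses the convention
#' \eqn{p_\lambda(|v|) = \lambda v^2} so the derivative is
#' \eqn{2\lambda|v|} (only the ratio to \eqn{|v|} matters downstream);
#' `NONE` gives 0.
#'
#' @param spec A [penalty_spec()].
#' @param v Loading value(s); only \eqn{|v|} is used.
#' @return Non-negative derivative value(s).
#' @export
penalty_derivative <- function(spec, v) {
  stopifnot(inherits(spec, "penalty_spec"))
  av <- abs(v)
  lam <- spec$lambda
  switch(spec$family,
    NONE  = rep(0, length(av)),
    LASSO = rep(lam, length(av)),
    RIDGE = 2 * lam * av,
    EN    = lam + 2 * spec$en_lambda2 * av,
    SCAD  = {
      a <- spec$scad_a
      ifelse(av <= lam, lam,
             pmax(a * lam - av, 0) / (a - 1))
    },
    HL    = {
      u <- solve_hl_scale(av, spec$theta, spec$w)
      # lambda * |v| / u; at v = 0 (u = 0 when w >= 2) the limit is
      # lambda * sqrt(theta) for w = 2 and +Inf for w > 2.  Callers use
      # the delta-perturbed magnitude, so av > 0 in practice.
      out <- lam * av / u
      out[av == 0 & u == 0] <- if (spec$w > 2) Inf else
        lam * sqrt(spec$theta)
      out
    })
}

#' Diagonal IWLS weights
#'
#' Entries of the diagonal weight matrix \eqn{W_{\lambda,\delta}} used
#' by the penalized regression step: entry \eqn{j} is
#' \eqn{p'_\lambda(\tilde v_j)/\tilde v_j} at the perturbed magnitude
#' \eqn{\tilde v_j = \sqrt{v_j^2 + \delta}}.  The perturbation keeps
#' every weight finite (the raw ratio is undefined at \eqn{v_j = 0});
#' with the default \eqn{\delta = 10^{-8}} the weight at zero is large
#' enough to pin the coordinate at (numerical) zero for sparse
#' families.  For the HL family the entry equals
#' \eqn{\lambda / \hat u_j(\tilde v_j)}.
#'
#' @param spec A [penalty_spec()].
#' @param v Current loading vector (finite).
#' @return Vector of positive, finite weights, same length as `v`.
#' @export
iwls_weights <- function(spec, v) {
  stopifnot(inherits(spec, "penalty_spec"), all(is.finite(v)))
  vt <- sqrt(v^2 + spec$delta)
  if (spec$family == "HL") {
    u <- solve_hl_scale(vt, spec$theta, spec$w)
    spec$lambda / u
  } else {
    penalty_derivative(spec, vt) / vt
  }
}
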