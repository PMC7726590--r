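#' Wald test for parameter differences between two fitted conditions
#'
#' Tests whether the free parameters fitted to two conditions come from
#' the same underlying values, using the Hessian-based covariance of each
#' fit: the statistic `t(dp) %*% solve(V_A + V_B) %*% dp` (with `dp` the
#' difference of the natural parameter vectors) is referred to a
#' chi-square distribution with `k` degrees of freedom. `p <= .05` counts
#' as the conditions being distinguished.
#'
#' @param fit_a,fit_b [fit_mle()] results for the same model on two
#'   datasets, fitted with `hessian = TRUE` (or with `vcov` present).
#' @param ridge Non-negative ridge added to the diagonal of the summed
#'   covariance before inversion; the default 0 errors on a singular
#'   covariance and suggests a small ridge instead.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
condition_compare <- function(fit_a, fit_b, ridge = 0) {
  stopifnot(inherits(fit_a, "wm_fit"), inherits(fit_b, "wm_fit"))
  if (fit_a$model$type != fit_b$model$type)
    stop("fits must use the same model")
  if (!fit_a$convergence || !fit_b$convergence)
    stop("both fits must have converged")
  if (is.null(fit_a$vcov) || is.null(fit_b$vcov))
    stop("fits need Hessian-based covariances; refit with `hessian = TRUE`")
  dp <- par_to_natural(fit_a$params, fit_a$model) -
    par_to_natural(fit_b$params, fit_b$model)
  V <- fit_a$vcov + fit_b$vcov + diag(ridge, length(dp))
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi))
    stop("singular summed covariance; retry with a small `ridge` ",
         "(e.g. 1e-8) or check that both fits are interior optima")
  stat <- as.numeric(t(dp) %*% Vi %*% dp)
  df <- length(dp)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
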