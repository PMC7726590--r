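#' Mixture-model parameters
#'
#' Bundles the mixing proportions and spread of the three-component mixture:
#' `alpha` (target responding), `beta` (misbinding, i.e. responses centred on
#' a nontarget), `gamma` (guessing), and the imprecision, expressed as the
#' per-axis standard deviation `sigma` of an isotropic bivariate Gaussian in
#' 2D or as the von Mises concentration `kappa` in 1D. `alpha` is always
#' derived as `1 - beta - gamma` (or `1 - beta1 - beta2 - gamma` for the
#' two-class model) and is never a free parameter.
#'
#' @param beta Misbinding proportion in `[0, 1]`.
#' @param gamma Guessing proportion in `[0, 1]`.
#' @param sigma Imprecision SD (length units, 2D models); `NULL` for 1D.
#' @param kappa von Mises concentration (1D models); `NULL` for 2D.
#' @param beta1,beta2 Class-specific misbinding proportions for the
#'   two-nontarget-class model; when supplied they replace `beta`.
#' @param bias Optional named numeric vector of bias parameters
#'   (`bias_x`/`bias_y` for a constant bias, `bias_prop` for proportional or
#'   radial biases).
#' @return An object of class `mixture_params`.
#' @examples
#' mixture_params(beta = 0.3, gamma = 0.3, sigma = 30)
#' @export
mixture_params <- function(beta = 0, gamma = 0, sigma = NULL, kappa = NULL,
                           beta1 = NULL, beta2 = NULL, bias = NULL) {
  two_class <- !is.null(beta1) || !is.null(beta2)
  if (two_class) {
    if (is.null(beta1) || is.null(beta2))
      stop("two-class parameters need both `beta1` and `beta2`")
    beta <- beta1 + beta2
  }
  stopifnot(is.numeric(beta), is.numeric(gamma))
  if (beta < -1e-12 || gamma < -1e-12 || beta > 1 + 1e-12 || gamma > 1 + 1e-12)
    stop("`beta` and `gamma` must lie in [0, 1]")
  alpha <- 1 - beta - gamma
  if (alpha < -1e-9)
    stop("mixing proportions exceed 1: alpha = 1 - beta - gamma is negative")
  alpha <- max(alpha, 0)
  if (!is.null(sigma)) {
    if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  }
  if (!is.null(kappa)) {
    if (!is.finite(kappa) || kappa < 0) stop("`kappa` must be non-negative")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 sigma = sigma, kappa = kappa,
                 beta1 = beta1, beta2 = beta2, bias = bias),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  spread <- if (!is.null(x$sigma)) sprintf("sigma = %.4g", x$sigma)
            else if (!is.null(x$kappa)) sprintf("kappa = %.4g", x$kappa)
            else "no spread parameter"
  betas <- if (!is.null(x$beta1))
    sprintf("beta1 = %.4g, beta2 = %.4g", x$beta1, x$beta2)
  else sprintf("beta = %.4g", x$beta)
  cat(sprintf("<mixture_params> alpha = %.4g, %s, gamma = %.4g, %s\n",
              x$alpha, betas, x$gamma, spread))
  if (!is.null(x$bias))
    cat("  bias:", paste(names(x$bias), signif(x$bias, 4), sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}

as_mixture_params <- function(params) {
  if (inherits(params, "mixture_params")) return(params)
  if (is.list(params)) return(do.call(mixture_params, params))
  stop("`params` must be a mixture_params object or a named list")
}
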