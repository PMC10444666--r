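# Likelihood-ratio tests, information criteria, and random-effect
# prediction.

#' Likelihood-ratio test between two nested fits
#'
#' Computes `LR = -2 (ll_r - ll_u)` and refers it to a central
#' chi-square distribution with degrees of freedom equal to the
#' difference in free-parameter counts.  Nestedness of the two models is
#' the caller's responsibility; the function checks only that the
#' degrees of freedom are positive and that the restricted model does
#' not fit better than the unrestricted one (beyond numerical noise,
#' which triggers a warning about a suspected optimizer failure).
#'
#' @param restricted,unrestricted Converged `mpt_fit` objects.
#' @return An object of class `mpt_lr` with elements `statistic`, `df`,
#'   `p_value`, and `crit_05` (the 0.95 chi-square quantile).
#' @examples
#' qchisq(0.95, df = 19)  # 30.14, the critical value at df = 19
#' @export
lr_test <- function(restricted, unrestricted) {
  df_r <- length(restricted$flat_estimates)
  df_u <- length(unrestricted$flat_estimates)
  df <- df_u - df_r
  if (df < 1L) stop("models have identical (or inverted) free-parameter counts",
                    call. = FALSE)
  lr <- -2 * (restricted$loglik - unrestricted$loglik)
  if (lr < -1e-6) {
    warning("restricted model fits better than the unrestricted one; ",
            "optimizer failure suspected")
  }
  lr <- max(lr, 0)
  structure(list(statistic = lr, df = df,
                 p_value = stats::pchisq(lr, df, lower.tail = FALSE),
                 crit_05 = stats::qchisq(0.95, df)),
            class = "mpt_lr")
}

#' @export
print.mpt_lr <- function(x, ...) {
  cat(sprintf("LR = %.3f, df = %d, p = %.4g (chi-square 5%% critical value: %.2f)\n",
              x$statistic, x$df, x$p_value, x$crit_05))
  invisible(x)
}

#' Information criteria of a fit
#'
#' `AIC = -2 ll + 2 df` and `BIC = -2 ll + log(n) df`, where `df` counts
#' the free parameters (`R` random means, `S - R` fixed intercepts, the
#' free covariate weights, and the `R(R+1)/2` covariance parameters) and
#' `n` is the total number of recorded responses across persons and
#' category systems.
#'
#' @param fit An `mpt_fit`.
#' @return Named vector with `AIC`, `BIC`, and `df`.
#' @export
information_criteria <- function(fit) {
  df <- length(fit$flat_estimates)
  n <- fit$n_obs
  c(AIC = -2 * fit$loglik + 2 * df,
    BIC = -2 * fit$loglik + log(n) * df,
    df = df)
}

#' @export
AIC.mpt_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * length(object$flat_estimates)
}

#' @export
BIC.mpt_fit <- function(object, ...) {
  unname(information_criteria(object)["BIC"])
}

#' Predict per-person random effects
#'
#' `"mode"` returns each person's maximizer of the joint log-density
#' (already available from estimation); `"empirical_bayes"` returns the
#' posterior mean of the random effects given the person's frequencies
#' and the fitted population parameters, approximated with the fit's own
#' quadrature back end.  Persons with no recorded responses get their
#' prior mean `mu_t` under both estimators.
#'
#' @param fit A converged `mpt_fit`.
#' @param estimator `"mode"` or `"empirical_bayes"`.
#' @return A T x R matrix of link-scale random-effect predictions,
#'   columns named after the random parameters.
#' @export
predict_random_effects <- function(fit, estimator = c("mode", "empirical_bayes")) {
  estimator <- match.arg(estimator)
  R <- sum(fit$params$random)
  out <- if (estimator == "mode") {
    fit$modes$modes
  } else {
    pre <- .fit_pre(fit$model, fit$params, fit$data, fit$settings$link)
    scheme <- .node_scheme(fit$settings$method, R, fit$settings$nodes,
                           fit$settings$qmc_points)
    .marginal_eval(pre, scheme, fit$modes, want_eb = TRUE)$eb
  }
  colnames(out) <- fit$params$parameters[fit$params$random]
  out
}
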