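#' Link functions mapping latent person parameters to probabilities
#'
#' The hierarchical model places multivariate-normal person effects on a
#' real-valued link scale; `link_inverse()` maps a link-scale value eta
#' to a probability (inverse logit or standard-normal CDF), and
#' `link_derivative()` gives d theta / d eta, used throughout the
#' analytical gradient.  `link_forward()` is the inverse map
#' (log-odds / normal quantile).  Inverse-link values are clamped to
#' `[1e-12, 1 - 1e-12]` so that downstream logarithms stay finite for
#' extreme random-effect draws.
#'
#' @param eta Numeric vector of finite link-scale values.
#' @param link `"probit"` (default, the latent-trait convention) or
#'   `"logit"`.
#' @param p Numeric vector of probabilities in (0, 1).
#' @return Numeric vector: probabilities in (0, 1) for `link_inverse`,
#'   strictly positive derivatives for `link_derivative`, link-scale
#'   values for `link_forward`.
#' @examples
#' link_inverse(0, "probit")        # 0.5
#' link_inverse(log(3), "logit")    # 0.75
#' link_derivative(0, "logit")      # 0.25
#' @export
link_inverse <- function(eta, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (any(!is.finite(eta))) stop("eta must be finite", call. = FALSE)
  p <- if (link == "probit") stats::pnorm(eta) else stats::plogis(eta)
  .clamp01(p)
}

#' @rdname link_inverse
#' @export
link_derivative <- function(eta, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (any(!is.finite(eta))) stop("eta must be finite", call. = FALSE)
  if (link == "probit") {
    stats::dnorm(eta)
  } else {
    p <- stats::plogis(eta)
    p * (1 - p)
  }
}

#' @rdname link_inverse
#' @export
link_forward <- function(p, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  if (link == "probit") stats::qnorm(p) else stats::qlogis(p)
}
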