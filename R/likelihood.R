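# Conditional (given random effects) likelihood, the per-person joint
# log-density, and the analytical score used by mode finding and by the
# marginal-gradient assembly.

# multivariate normal log-density via Cholesky
.dmvnorm_log <- function(x, mean, Sigma) {
  R <- length(mean)
  if (R == 0L) return(0)
  U <- chol(Sigma)
  d <- x - mean
  z <- backsolve(U, d, transpose = TRUE)
  -0.5 * R * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z * z)
}

# person-specific random-effect mean mu_t = mu + Gamma X_t
.mu_t <- function(params, X) {
  if (params$p > 0 && !is.null(X) && sum(params$random) > 0) {
    params$mu + drop(params$Gamma %*% X)
  } else {
    params$mu
  }
}

# link-scale predictor for every process parameter: random entries come
# from b, fixed entries from beta (+ gamma X)
.person_eta <- function(params, b, X) {
  rand <- params$random
  eta <- params$beta
  if (sum(rand) > 0) {
    if (length(b) != sum(rand)) {
      stop(sprintf("b must have length %d", sum(rand)), call. = FALSE)
    }
    eta[rand] <- b
  }
  if (params$p > 0 && any(!rand) && !is.null(X)) {
    if (length(X) != params$p) {
      stop(sprintf("X must have length %d", params$p), call. = FALSE)
    }
    eta[!rand] <- eta[!rand] + drop(params$gamma %*% X)
  }
  eta
}

#' Person-level process-parameter probabilities
#'
#' Maps a person's random-effect vector `b` (and covariates `X`) to the
#' vector of process-parameter probabilities: random parameters are
#' `link_inverse(b_s)`, fixed parameters are
#' `link_inverse(beta_s + gamma_s X)`.
#'
#' @param params An [mpt_params] object.
#' @param b Numeric vector of length R (random-effect values on the link
#'   scale).
#' @param X Optional covariate vector of length `params$p`.
#' @param link `"probit"` or `"logit"`.
#' @return Named probability vector of length S.
#' @export
person_theta <- function(params, b, X = NULL, link = c("probit", "logit")) {
  link <- match.arg(link)
  stats::setNames(link_inverse(.person_eta(params, b, X), link),
                  params$parameters)
}

#' Conditional and joint log-density of one person's frequencies
#'
#' `conditional_loglik()` is the log product-multinomial mass of one
#' person's category frequencies given their random effects (including
#' the multinomial coefficients, so values are comparable across
#' software).  `joint_logdensity()` adds the multivariate-normal
#' log-density of the random effects, i.e. the log of the integrand of
#' the person's marginal likelihood.
#'
#' @param model An `mpt_model`.
#' @param params An [mpt_params] object.
#' @param b Random-effect vector of length R.
#' @param person List with elements `n` (category counts, ordered as
#'   `model$cat_labels`) and optionally `X` (covariates).
#' @param link `"probit"` or `"logit"`.
#' @return Log-density (scalar).
#' @export
conditional_loglik <- function(model, params, b, person,
                               link = c("probit", "logit")) {
  link <- match.arg(link)
  n <- person$n
  if (length(n) != length(model$cat_labels)) {
    stop("person counts do not match the model's categories", call. = FALSE)
  }
  theta <- person_theta(params, b, person$X, link)
  P <- .cat_prob_matrix(model, matrix(theta, nrow = 1L))
  coef <- .log_multinom_coef(model, matrix(n, nrow = 1L))
  sum(n * log(pmax(P[1L, ], 1e-300))) + coef
}

#' @rdname conditional_loglik
#' @export
joint_logdensity <- function(model, params, b, person,
                             link = c("probit", "logit")) {
  link <- match.arg(link)
  conditional_loglik(model, params, b, person, link) +
    .dmvnorm_log(b, .mu_t(params, person$X), params$Sigma)
}

# d log f(n | theta) / d theta_s for one person:
#   sum_kj n_kj / P(C_kj) * sum_i P(B_kji) (a_skji/theta_s - b_skji/(1-theta_s))
# theta is clamped the same way as in probability evaluation so that the
# score is the exact derivative of the evaluated log-likelihood.
.dll_dtheta <- function(model, theta, n) {
  theta <- .clamp01(theta)
  logPB <- drop(log(theta) %*% t(model$A) + log1p(-theta) %*% t(model$B)) +
    model$const_log
  PB <- exp(logPB)
  J <- length(model$cat_names)
  Pcat <- vapply(seq_len(J), function(j) sum(PB[model$branch_cat == j]), 0)
  r_br <- (n / pmax(Pcat, 1e-300))[model$branch_cat]
  S <- length(theta)
  out <- numeric(S)
  for (s in seq_len(S)) {
    out[s] <- sum(r_br * PB * (model$A[, s] / theta[s] -
                                 model$B[, s] / (1 - theta[s])))
  }
  names(out) <- model$parameters
  out
}

#' Analytical score of the joint log-density
#'
#' Exact derivatives of [joint_logdensity()] with respect to every free
#' model parameter (in the flat parameterization: `beta`, covariate
#' weights, `mu`, `Gamma`, and the log-Cholesky factors of `Sigma`) and
#' with respect to the random-effect vector `b`.  The covariance
#' derivatives are propagated through the log-Cholesky factorization by
#' the chain rule; all components are validated against finite
#' differences in the test suite.
#'
#' @inheritParams conditional_loglik
#' @return List with elements `flat` (named gradient over free
#'   parameters) and `b` (gradient with respect to `b`, length R).
#' @export
score_components <- function(model, params, b, person,
                             link = c("probit", "logit")) {
  link <- match.arg(link)
  rand <- params$random
  R <- sum(rand)
  X <- person$X
  eta <- .person_eta(params, b, X)
  theta <- link_inverse(eta, link)
  gth <- .dll_dtheta(model, theta, person$n)
  geta <- gth * link_derivative(eta, link)

  flat <- c()
  if (any(!rand)) {
    gb <- stats::setNames(geta[!rand], paste0("beta.", params$parameters[!rand]))
    flat <- c(flat, gb)
    if (params$p > 0) {
      free <- which(params$gamma_mask)
      if (length(free)) {
        gg <- outer(geta[!rand], X)      # (S-R) x p
        idx <- arrayInd(free, dim(params$gamma))
        flat <- c(flat, stats::setNames(
          gg[free], paste0("gamma.", rownames(params$gamma)[idx[, 1]], ".", idx[, 2])))
      }
    }
  }
  grad_b <- numeric(R)
  if (R > 0) {
    mu_t <- .mu_t(params, X)
    Si <- chol2inv(chol(params$Sigma))
    u <- drop(Si %*% (b - mu_t))
    grad_b <- geta[rand] - u
    flat <- c(flat, stats::setNames(u, paste0("mu.", params$parameters[rand])))
    if (params$p > 0) {
      free <- which(params$Gamma_mask)
      if (length(free)) {
        gG <- outer(u, X)
        idx <- arrayInd(free, dim(params$Gamma))
        flat <- c(flat, stats::setNames(
          gG[free], paste0("Gamma.", rownames(params$Gamma)[idx[, 1]], ".", idx[, 2])))
      }
    }
    # d log phi / d Sigma = (u u' - Sigma^{-1}) / 2, then through L
    G <- 0.5 * (tcrossprod(u) - Si)
    L <- t(chol(params$Sigma))
    GL <- 2 * (G %*% L)
    dL <- GL
    diag(dL) <- diag(GL) * diag(L)       # log-diagonal chain rule
    ij <- which(lower.tri(diag(R), diag = TRUE), arr.ind = TRUE)
    flat <- c(flat, stats::setNames(dL[lower.tri(dL, diag = TRUE)],
                                    paste0("L.", ij[, 1], ".", ij[, 2])))
  }
  list(flat = flat, b = grad_b)
}
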