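# Marginal maximum-likelihood estimation: outer quasi-Newton
# maximization over the flat free parameters with the analytical
# marginal gradient, alternating with per-person mode refreshes
# (the classic two-step scheme), plus standard errors.

# aggregate-data fixed-effects fit used for starting values: maximize
# the multinomial log-likelihood of the pooled counts over the
# link-scale predictors of all S parameters
.aggregate_start <- function(model, data, link) {
  n_tot <- colSums(data$freq)
  S <- length(model$parameters)
  fn <- function(eta) {
    theta <- .clamp01(link_inverse(eta, link))
    P <- .cat_prob_matrix(model, matrix(theta, nrow = 1L))
    -sum(n_tot * log(pmax(P[1L, ], 1e-300)))
  }
  gr <- function(eta) {
    theta <- .clamp01(link_inverse(eta, link))
    -(.dll_dtheta(model, theta, n_tot) * link_derivative(eta, link))
  }
  res <- stats::optim(numeric(S), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  stats::setNames(pmin(pmax(res$par, -3), 3), model$parameters)
}

#' Fit a hierarchical MPT model by marginal maximum likelihood
#'
#' Maximizes the marginal log-likelihood (random effects integrated out
#' with the chosen back end) over all free parameters: intercepts of
#' fixed process parameters, link-scale means and covariance of random
#' process parameters, and covariate weights.  The optimizer is BFGS
#' with the analytical marginal gradient, alternating with per-person
#' mode refreshes until the log-likelihood stabilizes.  Starting values
#' come from a link-transformed aggregate-data fixed-effects fit with
#' `Sigma = 0.3 I`.  Estimation is deterministic given its inputs
#' (Halton sequences are deterministic).
#'
#' A fit counts as converged only if the outer iteration terminated
#' regularly, all estimates are finite, `Sigma` is positive definite,
#' and every standard error is defined and positive.
#'
#' @param model An `mpt_model` (restrictions already applied, or use
#'   `restrictions`).
#' @param data An [mpt_data] object, or a matrix/data frame of per-person
#'   category frequencies.
#' @param link `"probit"` (default) or `"logit"`.
#' @param method Integration back end: `"aghq"` (default), `"laplace"`,
#'   or `"qmc"`.
#' @param nodes AGHQ nodes per dimension.
#' @param qmc_points Number of Halton points for `"qmc"`.
#' @param random Names of the process parameters that vary across
#'   persons (default all).
#' @param restrictions Optional restrictions passed to
#'   [apply_restrictions()].
#' @param start Optional `mpt_params` starting values.
#' @param se `"grad_fd"` (default; finite differences of the analytical
#'   gradient), `"exact"`, or `"none"`.
#' @param control List of optimizer controls: `max_outer` (default 50),
#'   `inner_maxit` (30), `outer_tol` (1e-8), `grad_tol` (1e-4, scaled).
#' @return An object of class `mpt_fit`.
#' @examples
#' \donttest{
#' pop <- default_population()
#' sim <- simulate_mpt(pop, T = 40, counts = c(20, 5), seed = 7)
#' fit <- fit_mpt(pop$model, sim$data, method = "aghq", nodes = 3)
#' summary(fit)
#' }
#' @export
fit_mpt <- function(model, data, link = c("probit", "logit"),
                    method = c("aghq", "laplace", "qmc"),
                    nodes = 4L, qmc_points = 1000L,
                    random = NULL, restrictions = NULL,
                    start = NULL, se = c("grad_fd", "exact", "none"),
                    control = list()) {
  link <- match.arg(link)
  method <- match.arg(method)
  se <- match.arg(se)
  ctrl <- utils::modifyList(
    list(max_outer = 50L, inner_maxit = 30L, outer_tol = 1e-8,
         grad_tol = 1e-4, mode_tol = 1e-8), control)

  if (!is.null(restrictions)) model <- apply_restrictions(model, restrictions)
  if (!inherits(data, "mpt_data")) data <- mpt_data(data, model)
  if (nrow(data$freq) == 0L) stop("data is empty", call. = FALSE)
  if (is.null(random)) random <- model$parameters

  p <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  if (is.null(start)) {
    eta0 <- .aggregate_start(model, data, link)
    rand <- model$parameters %in% random
    start <- mpt_params(model, random = random,
                        beta = ifelse(rand, 0, eta0),
                        mu = eta0[rand], Sigma = diag(0.3, sum(rand)), p = p)
  }
  params <- start
  R <- sum(params$random)
  messages <- character(0)

  pre <- .fit_pre(model, params, data, link)
  scheme <- .node_scheme(method, R, nodes, qmc_points)

  flat <- flatten_params(params)
  modes <- .find_modes_pre(pre, grad_tol = ctrl$mode_tol)

  # One quasi-Newton run over the free parameters; the per-person modes
  # are refreshed (warm-started) at every objective evaluation, so the
  # surface being maximized is the adaptive approximation itself.  The
  # refreshed modes are cached so that fn and gr at the same point share
  # one mode search.
  cache <- new.env(parent = emptyenv())
  cache$modes <- modes
  cache$v <- NULL
  eval_at <- function(v, want_grad) {
    if (!is.null(cache$v) && identical(v, cache$v) &&
        (!want_grad || !is.null(cache$grad))) {
      return(cache)
    }
    prm <- unflatten_params(v, params)
    prl <- .fit_pre(model, prm, data, link)
    md <- .find_modes_pre(prl, warm_start = cache$modes,
                          grad_tol = ctrl$mode_tol, max_iter = 50L)
    ev <- .marginal_eval(prl, scheme, md, want_grad = want_grad)
    cache$v <- v
    cache$modes <- md
    cache$ll <- ev$total
    cache$grad <- if (want_grad) ev$grad
    cache
  }
  obj <- function(v) {
    val <- tryCatch(-eval_at(v, FALSE)$ll, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  grd <- function(v) {
    -eval_at(v, TRUE)$grad
  }
  opt <- stats::nlminb(flat, obj, grd,
                       control = list(rel.tol = ctrl$outer_tol * 1e-2,
                                      iter.max = ctrl$max_outer *
                                        ctrl$inner_maxit,
                                      eval.max = 2L * ctrl$max_outer *
                                        ctrl$inner_maxit))
  flat <- opt$par

  # Accept-only polish: a few damped two-step cycles (frozen-mode inner
  # solves, where the analytic gradient is exact, followed by a mode
  # refresh).  A cycle is kept only if it improves the refreshed
  # marginal log-likelihood; the first rejected or negligible cycle
  # certifies stationarity.
  terminated <- FALSE
  outer_it <- 0L
  ll_best <- -opt$objective
  modes <- cache$modes
  for (outer_it in seq_len(8L)) {
    frozen_obj <- function(v) {
      val <- tryCatch({
        prm <- unflatten_params(v, params)
        prl <- .fit_pre(model, prm, data, link)
        -.marginal_eval(prl, scheme, modes)$total
      }, error = function(e) NA_real_)
      if (!is.finite(val)) 1e10 else val
    }
    frozen_grd <- function(v) {
      prm <- unflatten_params(v, params)
      prl <- .fit_pre(model, prm, data, link)
      -.marginal_eval(prl, scheme, modes, want_grad = TRUE)$grad
    }
    io <- stats::nlminb(flat, frozen_obj, frozen_grd,
                        control = list(rel.tol = ctrl$outer_tol * 1e-3,
                                       iter.max = 10L))
    cand <- io$par
    prm <- unflatten_params(cand, params)
    prl <- .fit_pre(model, prm, data, link)
    md <- .find_modes_pre(prl, warm_start = modes, grad_tol = ctrl$mode_tol)
    ll_new <- .marginal_eval(prl, scheme, md)$total
    if (is.finite(ll_new) && ll_new > ll_best) {
      improve <- ll_new - ll_best
      flat <- cand
      modes <- md
      ll_best <- ll_new
      if (improve < ctrl$outer_tol * (abs(ll_new) + 1)) {
        terminated <- TRUE
        break
      }
    } else {
      terminated <- TRUE
      break
    }
  }
  cache$modes <- modes
  if (!terminated) {
    messages <- c(messages,
                  sprintf("polish still improving after %d cycles", outer_it))
  }
  params <- unflatten_params(flat, params)
  pre <- .fit_pre(model, params, data, link)
  modes <- .find_modes_pre(pre, warm_start = cache$modes,
                           grad_tol = ctrl$mode_tol)
  ev <- .marginal_eval(pre, scheme, modes, want_grad = TRUE)
  loglik <- ev$total
  grad <- ev$grad
  # gradient scaled per recorded response: at the reported optimum any
  # residual reflects the quadrature approximation, not optimizer slack
  grad_scaled <- max(abs(grad)) / max(1, sum(data$freq))
  if (any(modes$flagged)) {
    messages <- c(messages, sprintf("%d person mode(s) flagged",
                                    sum(modes$flagged)))
  }

  fit <- structure(
    list(model = model, data = data, params = params,
         flat_estimates = flat, loglik = loglik,
         n_obs = sum(data$freq), modes = modes,
         gradient = grad, grad_scaled = grad_scaled,
         converged = terminated && all(is.finite(flat)),
         messages = messages, outer_iterations = outer_it,
         settings = list(link = link, method = method, nodes = nodes,
                         qmc_points = qmc_points, random = random,
                         control = ctrl),
         std_errors = NULL, vcov = NULL),
    class = "mpt_fit")

  if (se != "none") {
    fit <- tryCatch(standard_errors(fit, method = se),
                    error = function(e) {
                      fit$converged <- FALSE
                      fit$messages <- c(fit$messages,
                                        paste("standard errors failed:",
                                              conditionMessage(e)))
                      fit
                    })
  }
  fit
}

# analytic marginal gradient at arbitrary flat parameters, with the
# modes refreshed (warm-started) at those parameters
.marginal_grad_at <- function(fit, flat, warm) {
  params <- unflatten_params(flat, fit$params)
  pre <- .fit_pre(fit$model, params, fit$data, fit$settings$link)
  modes <- .find_modes_pre(pre, warm_start = warm,
                           grad_tol = fit$settings$control$mode_tol)
  list(grad = .marginal_eval(pre, .node_scheme(fit$settings$method, pre$R,
                                               fit$settings$nodes,
                                               fit$settings$qmc_points),
                             modes, want_grad = TRUE)$grad,
       modes = modes)
}

#' Standard errors of a marginal ML fit
#'
#' `"grad_fd"` builds the observed information from central finite
#' differences of the analytical marginal gradient (modes refreshed at
#' each perturbed point); `"exact"` assembles the second-derivative
#' matrix from quadrature-approximated inner integrals of the score and
#' its derivative.  Standard errors are the square roots of the diagonal
#' of the inverse information.  A non-positive-definite information
#' matrix leaves the standard errors undefined and marks the fit as not
#' converged.
#'
#' @param fit An `mpt_fit`.
#' @param method `"grad_fd"` or `"exact"`.
#' @return The fit with `std_errors`, `vcov` (covariance of the flat
#'   estimates), and `sigma_table` (natural-scale variances/covariances
#'   with delta-method standard errors) filled in.
#' @export
standard_errors <- function(fit, method = c("grad_fd", "exact")) {
  method <- match.arg(method)
  flat <- fit$flat_estimates
  npar <- length(flat)
  H <- if (method == "grad_fd") {
    Hm <- matrix(0, npar, npar)
    warm <- fit$modes
    for (j in seq_len(npar)) {
      h <- 1e-4 * (1 + abs(flat[j]))
      up <- flat; up[j] <- up[j] + h
      dn <- flat; dn[j] <- dn[j] - h
      gu <- .marginal_grad_at(fit, up, warm)
      gd <- .marginal_grad_at(fit, dn, warm)
      Hm[, j] <- (gu$grad - gd$grad) / (2 * h)
    }
    (Hm + t(Hm)) / 2
  } else {
    .exact_hessian(fit)
  }

  info <- -H
  ok <- tryCatch({ U <- chol(info); TRUE }, error = function(e) FALSE)
  if (ok) {
    # chol can slip past an indefinite or numerically singular matrix
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || min(ev) / max(ev) < 1e-8) ok <- FALSE
  }
  if (!ok) {
    fit$std_errors <- rep(NA_real_, npar)
    fit$vcov <- NULL
    fit$converged <- FALSE
    fit$messages <- c(fit$messages,
                      "information matrix not positive definite; standard errors undefined")
    return(fit)
  }
  V <- chol2inv(U)
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(flat)
  fit$std_errors <- se
  fit$vcov <- V
  dimnames(fit$vcov) <- list(names(flat), names(flat))
  if (any(!is.finite(se)) || any(se <= 0)) {
    fit$converged <- FALSE
    fit$messages <- c(fit$messages, "undefined standard errors")
  }
  fit$sigma_table <- .sigma_delta(fit)
  fit
}

# Exact observed information: per person,
# quadrature-approximated posterior expectations of the score, the score
# outer product, and the (finite-difference) derivative of the score.
.exact_hessian <- function(fit, h = 1e-5) {
  flat <- fit$flat_estimates
  npar <- length(flat)
  pre <- .fit_pre(fit$model, fit$params, fit$data, fit$settings$link)
  scheme <- .node_scheme(fit$settings$method, pre$R, fit$settings$nodes,
                         fit$settings$qmc_points)
  modes <- fit$modes
  T_n <- pre$T_n

  person_scores <- function(v) {
    # per-person posterior-weighted score at flat parameters v
    prm <- unflatten_params(v, fit$params)
    prl <- .fit_pre(fit$model, prm, fit$data, fit$settings$link)
    sc <- matrix(0, T_n, npar)
    for (t in seq_len(T_n)) {
      dat_t <- structure(list(
        freq = fit$data$freq[t, , drop = FALSE],
        covariates = if (is.null(fit$data$covariates)) NULL
        else fit$data$covariates[t, , drop = FALSE],
        totals = NULL), class = "mpt_data")
      prl_t <- .fit_pre(fit$model, prm, dat_t, fit$settings$link)
      modes_t <- structure(list(modes = modes$modes[t, , drop = FALSE],
                                chol = modes$chol[t],
                                logdet_half = modes$logdet_half[t],
                                grad_norm = 0, flagged = FALSE),
                           class = "mode_set")
      sc[t, ] <- .marginal_eval(prl_t, scheme, modes_t, want_grad = TRUE)$grad
    }
    sc
  }

  s0 <- person_scores(flat)
  H <- matrix(0, npar, npar)
  for (j in seq_len(npar)) {
    hj <- h * (1 + abs(flat[j]))
    up <- flat; up[j] <- up[j] + hj
    dn <- flat; dn[j] <- dn[j] - hj
    H[, j] <- colSums(person_scores(up) - person_scores(dn)) / (2 * hj)
  }
  (H + t(H)) / 2
}

# natural-scale Sigma entries with delta-method SEs from the
# log-Cholesky covariance block
.sigma_delta <- function(fit) {
  params <- fit$params
  R <- sum(params$random)
  if (R == 0L || is.null(fit$vcov)) return(NULL)
  flat <- fit$flat_estimates
  nm <- names(flat)
  lidx <- grep("^L\\.", nm)
  ij <- which(lower.tri(diag(R), diag = TRUE), arr.ind = TRUE)
  nL <- nrow(ij)
  # Jacobian of vech(Sigma) w.r.t. the log-Cholesky entries (FD)
  Jm <- matrix(0, nL, nL)
  base <- flat[lidx]
  vech <- function(v) {
    L <- .logchol_inv(v, R)
    Sg <- L %*% t(L)
    Sg[lower.tri(Sg, diag = TRUE)]
  }
  for (j in seq_len(nL)) {
    h <- 1e-6 * (1 + abs(base[j]))
    up <- base; up[j] <- up[j] + h
    dn <- base; dn[j] <- dn[j] - h
    Jm[, j] <- (vech(up) - vech(dn)) / (2 * h)
  }
  Vl <- fit$vcov[lidx, lidx, drop = FALSE]
  Vs <- Jm %*% Vl %*% t(Jm)
  est <- params$Sigma[lower.tri(params$Sigma, diag = TRUE)]
  rn <- params$parameters[params$random]
  data.frame(
    component = paste0("Sigma.", rn[ij[, 1]], ".", rn[ij[, 2]]),
    estimate = est,
    se = sqrt(pmax(diag(Vs), 0)),
    row.names = NULL)
}

# ---- methods --------------------------------------------------------------

#' @export
print.mpt_fit <- function(x, ...) {
  cat(sprintf("Hierarchical MPT fit (%s%s, %s link)\n",
              x$settings$method,
              if (x$settings$method == "aghq")
                sprintf(", %d nodes/dim", x$settings$nodes)
              else if (x$settings$method == "qmc")
                sprintf(", %d Halton points", x$settings$qmc_points)
              else "",
              x$settings$link))
  cat(sprintf("log-likelihood: %.4f  (T = %d, responses = %d)\n",
              x$loglik, nrow(x$data$freq), x$n_obs))
  cat(sprintf("converged: %s\n", x$converged))
  if (length(x$messages)) cat("notes:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.mpt_fit <- function(object, ...) {
  est <- object$flat_estimates
  se <- object$std_errors
  if (is.null(se)) se <- rep(NA_real_, length(est))
  z <- est / se
  tab <- data.frame(estimate = est, se = se, z = z,
                    ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se)
  # probability-scale means of the random parameters
  rand <- object$params$random
  te <- link_inverse(object$params$mu, object$settings$link)
  out <- list(fit = object, coefficients = tab,
              prob_means = stats::setNames(te, names(object$params$mu)),
              sigma = object$params$Sigma, sigma_table = object$sigma_table,
              ic = information_criteria(object))
  class(out) <- "summary.mpt_fit"
  out
}

#' @export
print.summary.mpt_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nFree-parameter estimates (link / log-Cholesky scale):\n")
  print(round(x$coefficients, digits))
  if (length(x$prob_means)) {
    cat("\nProbability-scale means of random parameters:\n")
    print(round(x$prob_means, digits))
  }
  if (!is.null(x$sigma_table)) {
    cat("\nRandom-effect (co)variances (link scale):\n")
    print(x$sigma_table, digits = digits)
  }
  cat(sprintf("\nAIC: %.2f  BIC: %.2f  (df = %d)\n",
              x$ic["AIC"], x$ic["BIC"], x$ic["df"]))
  invisible(x)
}

#' @export
coef.mpt_fit <- function(object, ...) object$flat_estimates

#' @export
logLik.mpt_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$flat_estimates),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.mpt_fit <- function(object, ...) object$vcov
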