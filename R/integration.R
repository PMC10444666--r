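# Approximation of each person's marginal-likelihood integral by the
# Laplace approximation, adaptive Gauss-Hermite quadrature (AGHQ), or
# mode-scaled Quasi Monte Carlo with Halton points.  All three back ends
# share one stacked evaluator (.marginal_eval) that evaluates every
# person's nodes in a handful of matrix operations.

.FIRST_PRIMES <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
                   53, 59, 61, 67, 71, 73, 79, 83, 89, 97)

#' Halton low-discrepancy points
#'
#' Deterministic radical-inverse sequence: dimension r uses the r-th
#' prime as base, and the zero point (index 0) is skipped, so all points
#' lie strictly inside the open unit hypercube.
#'
#' @param dim Number of dimensions (at most 25).
#' @param n Number of points.
#' @return An `n` x `dim` matrix with entries in (0, 1).
#' @examples
#' halton_points(1, 3)   # 1/2, 1/4, 3/4
#' halton_points(2, 1)   # 1/2, 1/3
#' @export
halton_points <- function(dim, n) {
  if (dim < 1 || dim > length(.FIRST_PRIMES)) {
    stop(sprintf("dim must be between 1 and %d", length(.FIRST_PRIMES)),
         call. = FALSE)
  }
  idx <- seq_len(n)
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    base <- .FIRST_PRIMES[d]
    i <- idx
    f <- 1 / base
    r <- numeric(n)
    while (any(i > 0)) {
      r <- r + (i %% base) * f
      i <- i %/% base
      f <- f / base
    }
    out[, d] <- r
  }
  out
}

# Gauss-Hermite nodes/weights for the physicists' weight exp(-x^2)
.gh_nodes <- function(M) {
  if (M == 1L) return(list(x = 0, w = sqrt(pi)))
  gh <- pracma::gaussHermite(M)
  list(x = gh$x, w = gh$w)
}

# ---- per-person precomputation -------------------------------------------

# Everything about (model, params, data, link) that does not depend on b:
# per-person fixed-part link predictors, random-effect means, counts,
# multinomial coefficients, and Sigma factorizations.
.fit_pre <- function(model, params, data, link) {
  rand <- params$random
  R <- sum(rand)
  T_n <- nrow(data$freq)
  X <- data$covariates
  eta_fix <- NULL
  if (any(!rand)) {
    eta_fix <- matrix(params$beta[!rand], T_n, sum(!rand), byrow = TRUE)
    if (params$p > 0 && !is.null(X)) {
      eta_fix <- eta_fix + X %*% t(params$gamma)
    }
  }
  mu_t <- NULL
  Si <- NULL
  ldet_half <- 0
  if (R > 0) {
    mu_t <- matrix(params$mu, T_n, R, byrow = TRUE)
    if (params$p > 0 && !is.null(X)) {
      mu_t <- mu_t + X %*% t(params$Gamma)
    }
    # tiny ridge guards against diagonal underflow of the log-Cholesky
    # parameterization during line searches
    U <- tryCatch(chol(params$Sigma),
                  error = function(e) chol(params$Sigma + 1e-10 * diag(R)))
    Si <- chol2inv(U)
    ldet_half <- sum(log(diag(U)))
  }
  list(model = model, params = params, link = link, T_n = T_n, R = R,
       rand = rand, X = X, eta_fix = eta_fix, mu_t = mu_t, Si = Si,
       ldet_half = ldet_half, counts = data$freq,
       coef = .log_multinom_coef(model, data$freq))
}

#' Per-person modes of the joint log-density
#'
#' Maximizes each person's joint log-density (conditional log-likelihood
#' plus random-effect log-density) over the random-effect vector, and
#' returns the modes together with the mode-curvature matrices
#' `Omega_t` (inverse negative Hessian at the mode) used by all three
#' integration back ends.  Warm starts from a previous mode set make the
#' repeated refreshes of the outer two-step estimation cheap.
#'
#' @param model An `mpt_model`.
#' @param params An [mpt_params] object.
#' @param data An [mpt_data] object.
#' @param link `"probit"` or `"logit"`.
#' @param warm_start Optional mode set from a previous call.
#' @param grad_tol Gradient-norm tolerance certifying each mode.
#' @param max_iter Newton iteration cap per person.
#' @return A `mode_set`: list with `modes` (T x R), `chol` (list of lower
#'   Cholesky factors of `Omega_t`), `logdet_half` (per-person
#'   `log|Omega_t|/2`), `grad_norm`, and `flagged` (persons that failed
#'   to converge or had non-positive-definite curvature).
#' @export
find_modes <- function(model, params, data, link = c("probit", "logit"),
                       warm_start = NULL, grad_tol = 1e-8, max_iter = 100L) {
  link <- match.arg(link)
  pre <- .fit_pre(model, params, data, link)
  .find_modes_pre(pre, warm_start, grad_tol, max_iter)
}

# joint log-density (and b-gradient) for all persons at once: B is a
# T x R matrix of candidate random-effect vectors, one row per person
.stack_joint <- function(pre, B, want_grad = FALSE) {
  S <- length(pre$rand)
  T_n <- pre$T_n
  Eta <- matrix(0, T_n, S)
  Eta[, pre$rand] <- B
  if (any(!pre$rand)) Eta[, !pre$rand] <- pre$eta_fix
  Theta <- .clamp01(if (pre$link == "probit") stats::pnorm(Eta) else stats::plogis(Eta))
  res <- .condll_block(pre$model, Theta, pre$counts, pre$coef, want_grad)
  D <- B - pre$mu_t
  DSi <- D %*% pre$Si
  ll <- res$ll - 0.5 * pre$R * log(2 * pi) - pre$ldet_half -
    0.5 * rowSums(DSi * D)
  out <- list(ll = ll)
  if (want_grad) {
    dlink <- if (pre$link == "probit") stats::dnorm(Eta) else Theta * (1 - Theta)
    out$grad <- (res$dth * dlink)[, pre$rand, drop = FALSE] - DSi
  }
  out
}

# finite-difference Hessians of the joint log-density in b for all
# persons (2R stacked gradient evaluations); kept as an independent
# cross-check of the analytic Hessian
.stack_hess_fd <- function(pre, B, h = 1e-5) {
  R <- pre$R
  T_n <- pre$T_n
  cols <- vector("list", R)
  for (l in seq_len(R)) {
    Bp <- B; Bp[, l] <- Bp[, l] + h
    Bm <- B; Bm[, l] <- Bm[, l] - h
    cols[[l]] <- (.stack_joint(pre, Bp, TRUE)$grad -
                    .stack_joint(pre, Bm, TRUE)$grad) / (2 * h)
  }
  lapply(seq_len(T_n), function(t) {
    H <- vapply(cols, function(cl) cl[t, ], numeric(R))
    (H + t(H)) / 2
  })
}

# Exact Hessians of the joint log-density in b, one R x R matrix per
# person.  With ll = sum_c n_c log P_c, P_c = sum_{br in c} P(B_br),
# and u_s = a_s/theta_s - b_s/(1-theta_s) per branch,
#   d P_c / d theta_s           = sum_br PB u_s
#   d2 P_c / d theta_s theta_s' = sum_br PB (u_s u_s' + [s==s'] du_s)
# with du_s = -a_s/theta_s^2 - b_s/(1-theta_s)^2, and the chain rule
# through the link adds the second link derivative on the diagonal.
.stack_hess <- function(pre, B) {
  m <- pre$model
  S <- length(pre$rand)
  T_n <- pre$T_n
  R <- pre$R
  ridx <- which(pre$rand)
  Eta <- matrix(0, T_n, S)
  Eta[, pre$rand] <- B
  if (any(!pre$rand)) Eta[, !pre$rand] <- pre$eta_fix
  Theta <- .clamp01(if (pre$link == "probit") stats::pnorm(Eta) else stats::plogis(Eta))

  logPB <- log(Theta) %*% t(m$A) + log1p(-Theta) %*% t(m$B)
  if (any(m$const_log != 0)) logPB <- logPB + rep(m$const_log, each = T_n)
  PB <- exp(logPB)
  J <- length(m$cat_names)
  Mbc <- matrix(0, nrow(m$A), J)
  Mbc[cbind(seq_along(m$branch_cat), m$branch_cat)] <- 1
  Pcat <- pmax(PB %*% Mbc, 1e-300)
  Rmat <- (pre$counts / Pcat)[, m$branch_cat, drop = FALSE]
  RPB <- Rmat * PB
  R2 <- pre$counts / Pcat^2

  # link derivatives (only random columns are needed)
  if (pre$link == "probit") {
    d1 <- stats::dnorm(Eta)
    d2 <- -Eta * d1
  } else {
    d1 <- Theta * (1 - Theta)
    d2 <- d1 * (1 - 2 * Theta)
  }

  U <- vector("list", R)      # u_s per (person, branch), random s only
  Q <- vector("list", R)      # d P_c / d theta_s
  dth <- matrix(0, T_n, R)    # d ll / d theta_s
  for (l in seq_len(R)) {
    s <- ridx[l]
    U[[l]] <- outer(1 / Theta[, s], m$A[, s]) -
      outer(1 / (1 - Theta[, s]), m$B[, s])
    Q[[l]] <- (PB * U[[l]]) %*% Mbc
    dth[, l] <- rowSums(RPB * U[[l]])
  }

  Harr <- array(0, c(T_n, R, R))
  for (l in seq_len(R)) {
    s <- ridx[l]
    for (k in l:R) {
      s2 <- ridx[k]
      t1 <- rowSums(RPB * U[[l]] * U[[k]])
      if (k == l) {
        dU <- -(outer(1 / Theta[, s]^2, m$A[, s]) +
                  outer(1 / (1 - Theta[, s])^2, m$B[, s]))
        t1 <- t1 + rowSums(RPB * dU)
      }
      t2 <- rowSums(R2 * Q[[l]] * Q[[k]])
      d2ll <- t1 - t2
      h <- d2ll * d1[, s] * d1[, s2]
      if (k == l) h <- h + dth[, l] * d2[, s]
      Harr[, l, k] <- h
      Harr[, k, l] <- h
    }
  }
  lapply(seq_len(T_n), function(t) {
    matrix(Harr[t, , ], R, R) - pre$Si
  })
}

# one round of per-person backtracking Newton steps; returns updated B
.mode_step <- function(pre, B, st, act, steps) {
  alpha <- rep(1, pre$T_n)
  Bnew <- B
  Bnew[act, ] <- B[act, , drop = FALSE] + steps[act, , drop = FALSE]
  for (bt in 1:30) {
    cand <- B + alpha * (Bnew - B)
    lln <- .stack_joint(pre, cand)$ll
    bad <- act[!is.finite(lln[act]) | lln[act] < st$ll[act] - 1e-12]
    if (!length(bad)) break
    alpha[bad] <- alpha[bad] / 2
    if (all(alpha[bad] < 1e-8)) { alpha[bad] <- 0; break }
  }
  B + alpha * (Bnew - B)
}

.find_modes_pre <- function(pre, warm_start = NULL, grad_tol = 1e-8,
                            max_iter = 100L) {
  T_n <- pre$T_n
  R <- pre$R
  chols <- vector("list", T_n)
  flagged <- logical(T_n)
  if (R == 0L) {
    return(structure(list(modes = matrix(0, T_n, 0), chol = chols,
                          logdet_half = numeric(T_n),
                          grad_norm = numeric(T_n), flagged = flagged),
                     class = "mode_set"))
  }
  B <- if (!is.null(warm_start)) warm_start$modes else pre$mu_t
  st <- .stack_joint(pre, B, want_grad = TRUE)

  for (it in seq_len(max_iter)) {
    gn <- sqrt(rowSums(st$grad^2))
    act <- which(gn >= grad_tol & is.finite(gn))
    if (!length(act)) break
    Hs <- .stack_hess(pre, B)
    steps <- matrix(0, T_n, R)
    for (t in act) {
      nH <- -Hs[[t]]
      Uh <- tryCatch(chol(nH), error = function(e) NULL)
      if (is.null(Uh)) {
        ridge <- 1e-4 * max(1, max(abs(diag(nH))))
        while (is.null(Uh) && ridge <= 1e8) {
          Uh <- tryCatch(chol(nH + ridge * diag(R)), error = function(e) NULL)
          ridge <- ridge * 10
        }
      }
      if (is.null(Uh)) { flagged[t] <- TRUE; next }
      steps[t, ] <- backsolve(Uh, backsolve(Uh, st$grad[t, ], transpose = TRUE))
    }
    B <- .mode_step(pre, B, st, act, steps)
    st <- .stack_joint(pre, B, want_grad = TRUE)
  }
  grad_norm <- sqrt(rowSums(st$grad^2))
  flagged <- flagged | (grad_norm >= pmax(grad_tol, 1e-6))
  Hs <- .stack_hess(pre, B)
  logdet_half <- numeric(T_n)
  for (t in seq_len(T_n)) {
    Omega <- tryCatch(chol2inv(chol(-Hs[[t]])), error = function(e) NULL)
    if (is.null(Omega)) {             # non-PD curvature: fall back to Sigma
      flagged[t] <- TRUE
      Omega <- pre$params$Sigma
    }
    Lw <- t(chol(Omega))
    chols[[t]] <- Lw
    logdet_half[t] <- sum(log(diag(Lw)))
  }
  structure(list(modes = B, chol = chols, logdet_half = logdet_half,
                 grad_norm = grad_norm, flagged = flagged),
            class = "mode_set")
}

# ---- stacked marginal evaluation -----------------------------------------

# Quadrature/sampling nodes in standardized coordinates plus their log
# weights.  The per-person transform is b = mode_t + scale * C_t z with
# C_t the lower Cholesky factor of Omega_t; the person-independent parts
# of the log integration weights are returned here.
.node_scheme <- function(method, R, nodes, qmc_points, max_nodes = 1e6) {
  if (R == 0L) {
    return(list(Z = matrix(0, 1, 0), logw = 0, scale = 1))
  }
  if (method == "laplace") {
    list(Z = matrix(0, 1, R), logw = (R / 2) * log(2 * pi), scale = 1)
  } else if (method == "aghq") {
    if (nodes^R > max_nodes) {
      stop(sprintf(paste0("AGHQ with %d nodes per dimension and R = %d needs ",
                          "%g node vectors per person; use method = 'qmc'"),
                   nodes, R, nodes^R), call. = FALSE)
    }
    gh <- .gh_nodes(nodes)
    Z <- as.matrix(expand.grid(rep(list(gh$x), R)))
    dimnames(Z) <- NULL
    LW <- as.matrix(expand.grid(rep(list(log(gh$w)), R)))
    logw <- rowSums(LW) + rowSums(Z * Z) + (R / 2) * log(2)
    list(Z = Z, logw = logw, scale = sqrt(2))
  } else if (method == "qmc") {
    Z <- stats::qnorm(halton_points(R, qmc_points))
    logw <- (R / 2) * log(2 * pi) + 0.5 * rowSums(Z * Z) - log(qmc_points)
    list(Z = Z, logw = logw, scale = 1)
  } else {
    stop("unknown integration method: ", method, call. = FALSE)
  }
}

# One pass over all persons' nodes.  Returns the total and per-person
# marginal log-likelihood and, on request, the analytical gradient of
# the (quadrature-approximated) marginal log-likelihood with the modes
# held fixed, and/or empirical-Bayes posterior means.
.marginal_eval <- function(pre, scheme, modes, want_grad = FALSE,
                           want_eb = FALSE) {
  model <- pre$model
  params <- pre$params
  T_n <- pre$T_n
  R <- pre$R
  S <- length(pre$rand)
  rand <- pre$rand

  # R = 0: the marginal likelihood is the plain product multinomial
  if (R == 0L) {
    Eta <- pre$eta_fix
    Theta <- .clamp01(if (pre$link == "probit") stats::pnorm(Eta) else stats::plogis(Eta))
    res <- .condll_block(model, Theta, pre$counts, pre$coef, want_grad)
    out <- list(total = sum(res$ll), per_person = res$ll)
    if (want_grad) {
      out$grad <- .assemble_grad(pre, rep(1, T_n), res$dth, Eta, NULL, NULL,
                                 seq_len(T_n))
    }
    if (want_eb) out$eb <- matrix(0, T_n, 0)
    return(out)
  }

  Mr <- nrow(scheme$Z)
  n <- T_n * Mr
  grp <- rep(seq_len(T_n), each = Mr)

  # per-person affine transform of the standardized nodes
  Bbig <- matrix(0, n, R)
  for (t in seq_len(T_n)) {
    rows <- ((t - 1L) * Mr + 1L):(t * Mr)
    Bbig[rows, ] <- matrix(modes$modes[t, ], Mr, R, byrow = TRUE) +
      scheme$scale * scheme$Z %*% t(modes$chol[[t]])
  }

  Eta <- matrix(0, n, S)
  Eta[, rand] <- Bbig
  if (any(!rand)) Eta[, !rand] <- pre$eta_fix[grp, , drop = FALSE]
  Theta <- .clamp01(if (pre$link == "probit") stats::pnorm(Eta) else stats::plogis(Eta))

  counts_e <- pre$counts[grp, , drop = FALSE]
  res <- .condll_block(model, Theta, counts_e, pre$coef[grp], want_grad)

  # Gaussian log-density of the nodes under MVN(mu_t, Sigma)
  D <- Bbig - pre$mu_t[grp, , drop = FALSE]
  DSi <- D %*% pre$Si
  logphi <- -0.5 * R * log(2 * pi) - pre$ldet_half - 0.5 * rowSums(DSi * D)

  lw <- res$ll + logphi + rep(scheme$logw, T_n) + modes$logdet_half[grp]
  LW <- matrix(lw, nrow = Mr)
  mx <- apply(LW, 2L, max)
  ll_t <- mx + log(colSums(exp(sweep(LW, 2L, mx, "-"))))

  out <- list(total = sum(ll_t), per_person = ll_t)
  if (want_grad || want_eb) {
    omega <- exp(lw - ll_t[grp])      # normalized posterior node weights
    if (want_grad) {
      out$grad <- .assemble_grad(pre, omega, res$dth, Eta, DSi, Bbig, grp)
    }
    if (want_eb) {
      out$eb <- rowsum(omega * Bbig, grp)
    }
  }
  out
}

# conditional log-likelihood (and optionally d ll / d theta) for a block
# of parameter rows
.condll_block <- function(model, Theta, counts, coef, want_dtheta = FALSE) {
  logPB <- log(Theta) %*% t(model$A) + log1p(-Theta) %*% t(model$B)
  if (any(model$const_log != 0)) {
    logPB <- logPB + rep(model$const_log, each = nrow(logPB))
  }
  PB <- exp(logPB)
  J <- length(model$cat_names)
  Mbc <- matrix(0, nrow(model$A), J)
  Mbc[cbind(seq_along(model$branch_cat), model$branch_cat)] <- 1
  Pcat <- PB %*% Mbc
  Pcat_s <- pmax(Pcat, 1e-300)
  ll <- rowSums(counts * log(Pcat_s)) + coef
  out <- list(ll = ll)
  if (want_dtheta) {
    Rmat <- (counts / Pcat_s)[, model$branch_cat, drop = FALSE]
    W <- Rmat * PB
    out$dth <- (W %*% model$A) / Theta - (W %*% model$B) / (1 - Theta)
  }
  out
}

# weighted assembly of the marginal gradient over the flat free
# parameters: posterior-weighted expectation of the joint score at the
# quadrature nodes, one term per person
.assemble_grad <- function(pre, omega, dth, Eta, DSi, Bbig, grp) {
  params <- pre$params
  rand <- pre$rand
  R <- pre$R
  dlink <- if (pre$link == "probit") stats::dnorm(Eta) else {
    P <- stats::plogis(Eta); P * (1 - P)
  }
  deta <- dth * dlink
  Xe <- if (params$p > 0 && !is.null(pre$X)) pre$X[grp, , drop = FALSE] else NULL

  g <- c()
  if (any(!rand)) {
    gb <- drop(crossprod(omega, deta[, !rand, drop = FALSE]))
    g <- c(g, stats::setNames(gb, paste0("beta.", params$parameters[!rand])))
    if (params$p > 0) {
      free <- which(params$gamma_mask)
      if (length(free)) {
        gg <- crossprod(deta[, !rand, drop = FALSE] * omega, Xe)  # (S-R) x p
        idx <- arrayInd(free, dim(params$gamma))
        g <- c(g, stats::setNames(
          gg[free], paste0("gamma.", rownames(params$gamma)[idx[, 1]], ".", idx[, 2])))
      }
    }
  }
  if (R > 0) {
    gmu <- drop(crossprod(omega, DSi))
    g <- c(g, stats::setNames(gmu, paste0("mu.", params$parameters[rand])))
    if (params$p > 0) {
      free <- which(params$Gamma_mask)
      if (length(free)) {
        gG <- crossprod(DSi * omega, Xe)
        idx <- arrayInd(free, dim(params$Gamma))
        g <- c(g, stats::setNames(
          gG[free], paste0("Gamma.", rownames(params$Gamma)[idx[, 1]], ".", idx[, 2])))
      }
    }
    # Sigma block: sum_m omega (u u' - Si)/2, through the log-Cholesky map
    W <- crossprod(DSi, DSi * omega)
    G <- 0.5 * (W - sum(omega) * pre$Si)
    L <- t(tryCatch(chol(params$Sigma),
                    error = function(e) chol(params$Sigma + 1e-10 * diag(R))))
    GL <- 2 * (G %*% L)
    dL <- GL
    diag(dL) <- diag(GL) * diag(L)
    ij <- which(lower.tri(diag(R), diag = TRUE), arr.ind = TRUE)
    g <- c(g, stats::setNames(dL[lower.tri(dL, diag = TRUE)],
                              paste0("L.", ij[, 1], ".", ij[, 2])))
  }
  g
}

#' Marginal log-likelihood of a hierarchical MPT model
#'
#' Approximates each person's marginal likelihood integral (random
#' effects integrated out) with the chosen back end and returns the
#' summed and per-person log-likelihood values.
#'
#' * `"laplace"`: Gaussian approximation around each person's mode;
#'   exactly AGHQ with one node.
#' * `"aghq"`: tensor-product Gauss-Hermite rule with `nodes` nodes per
#'   dimension (`nodes^R` node vectors per person), recentered and
#'   rescaled per person by the mode and curvature.
#' * `"qmc"`: `qmc_points` Halton points mapped through the normal
#'   quantile, affinely transformed per person by the mode and curvature,
#'   with the importance-weight correction that makes the estimator
#'   consistent for the marginal integral.
#'
#' All accumulation is in log space via log-sum-exp.
#'
#' @inheritParams find_modes
#' @param method `"laplace"`, `"aghq"`, or `"qmc"`.
#' @param nodes AGHQ nodes per dimension.
#' @param qmc_points Number of Halton points.
#' @param modes Optional precomputed [find_modes()] result (must be
#'   current for `params`).
#' @return List with `total` (scalar log-likelihood), `per_person`
#'   (length-T vector), and `modes` (the mode set used).
#' @export
marginal_loglik <- function(model, params, data, link = c("probit", "logit"),
                            method = c("aghq", "laplace", "qmc"),
                            nodes = 5L, qmc_points = 1000L, modes = NULL) {
  link <- match.arg(link)
  method <- match.arg(method)
  pre <- .fit_pre(model, params, data, link)
  if (is.null(modes)) modes <- .find_modes_pre(pre)
  scheme <- .node_scheme(method, pre$R, nodes, qmc_points)
  out <- .marginal_eval(pre, scheme, modes)
  out$modes <- modes
  out
}
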