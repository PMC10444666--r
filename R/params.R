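#' Parameter set for a hierarchical MPT model
#'
#' Collects the estimable quantities of the latent-trait MPT model: the
#' intercepts `beta` of the fixed (non-varying) process parameters, the
#' means `mu` and covariance `Sigma` of the random (person-varying)
#' process parameters on the link scale, and optional covariate-weight
#' matrices `gamma` (fixed part) and `Gamma` (random part).  The mean
#' structure is identified by fixing the `beta` entries of random
#' parameters to zero; when all parameters are random, `beta` is
#' identically zero.
#'
#' @param model An `mpt_model`.
#' @param random Character vector naming the process parameters that
#'   vary across persons (default: all of them).
#' @param beta Named or ordered numeric vector of link-scale intercepts
#'   for the fixed parameters (length S; random entries are forced to 0).
#'   A scalar is recycled.
#' @param mu Link-scale means of the random parameters (length R).
#' @param Sigma R x R symmetric positive-definite link-scale covariance.
#' @param p Number of person-level covariates (0 for none).
#' @param gamma (S-R) x p covariate weights for the fixed parameters
#'   (rows named by fixed parameters), or `NULL`.
#' @param Gamma R x p covariate weights for the random parameters, or
#'   `NULL`.
#' @param gamma_mask,Gamma_mask Logical matrices marking which weights
#'   are free (estimated); `FALSE` entries are structural zeros.  Default
#'   all free.
#' @return An object of class `mpt_params`.
#' @export
mpt_params <- function(model, random = model$parameters,
                       beta = 0, mu = 0, Sigma = NULL,
                       p = 0L, gamma = NULL, Gamma = NULL,
                       gamma_mask = NULL, Gamma_mask = NULL) {
  pars <- model$parameters
  S <- length(pars)
  if (!all(random %in% pars)) {
    stop("'random' must name model parameters", call. = FALSE)
  }
  rand <- pars %in% random
  R <- sum(rand)

  beta_full <- numeric(S)
  names(beta_full) <- pars
  if (!is.null(names(beta))) {
    beta_full[names(beta)] <- beta
  } else {
    beta_full[] <- beta
  }
  beta_full[rand] <- 0

  mu <- rep_len(mu, R)
  names(mu) <- pars[rand]
  if (is.null(Sigma)) Sigma <- diag(0.3, R)
  Sigma <- as.matrix(Sigma)
  if (R > 0 && (nrow(Sigma) != R || ncol(Sigma) != R)) {
    stop(sprintf("Sigma must be %d x %d", R, R), call. = FALSE)
  }
  if (R > 0) .check_pd(Sigma, "Sigma")

  p <- as.integer(p)
  nfix <- S - R
  if (p > 0) {
    if (is.null(gamma)) gamma <- matrix(0, nfix, p)
    if (is.null(Gamma)) Gamma <- matrix(0, R, p)
    gamma <- as.matrix(gamma); Gamma <- as.matrix(Gamma)
    stopifnot(nrow(gamma) == nfix, ncol(gamma) == p,
              nrow(Gamma) == R, ncol(Gamma) == p)
    rownames(gamma) <- pars[!rand]
    rownames(Gamma) <- pars[rand]
    if (is.null(gamma_mask)) gamma_mask <- matrix(TRUE, nfix, p)
    if (is.null(Gamma_mask)) Gamma_mask <- matrix(TRUE, R, p)
    gamma[!gamma_mask] <- 0
    Gamma[!Gamma_mask] <- 0
  } else {
    gamma <- Gamma <- NULL
    gamma_mask <- Gamma_mask <- NULL
  }

  structure(
    list(parameters = pars, random = rand, beta = beta_full,
         mu = mu, Sigma = Sigma, p = p,
         gamma = gamma, Gamma = Gamma,
         gamma_mask = gamma_mask, Gamma_mask = Gamma_mask),
    class = "mpt_params")
}

.check_pd <- function(M, what = "matrix") {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  }
  ok <- tryCatch({ chol(M); TRUE }, error = function(e) FALSE)
  if (!ok) stop(sprintf("%s must be positive definite", what), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.mpt_params <- function(x, ...) {
  R <- sum(x$random)
  cat(sprintf("mpt_params: S = %d (%d random), p = %d covariates\n",
              length(x$parameters), R, x$p))
  if (R < length(x$parameters)) {
    cat("beta (fixed):\n"); print(x$beta[!x$random])
  }
  if (R > 0) {
    cat("mu:\n"); print(x$mu)
    cat("Sigma:\n"); print(x$Sigma)
  }
  invisible(x)
}

# ---- flat parameter map (free parameters <-> one real vector) -------------
#
# Order: beta[fixed], gamma[free], mu, Gamma[free], log-Cholesky of Sigma
# (column-major lower triangle; log on the diagonal).  The log-Cholesky
# parameterization keeps Sigma positive definite under unconstrained
# outer optimization.

.logchol <- function(Sigma) {
  L <- t(chol(Sigma))
  v <- L[lower.tri(L, diag = TRUE)]
  d <- diag(nrow(Sigma))
  di <- which(d[lower.tri(d, diag = TRUE)] == 1)
  v[di] <- log(v[di])
  v
}

.logchol_inv <- function(v, R) {
  L <- matrix(0, R, R)
  L[lower.tri(L, diag = TRUE)] <- v
  diag(L) <- exp(diag(L))
  L
}

#' Flat parameter map
#'
#' `flatten_params()` packs all free entries of an [mpt_params] object
#' into one named real vector, ordered as: fixed-parameter intercepts
#' `beta`, free `gamma` weights, random-effect means `mu`, free `Gamma`
#' weights, and the log-Cholesky factors of `Sigma` (column-major lower
#' triangle, logarithm on the diagonal).  `unflatten_params()` inverts
#' the map; any real vector decodes to a valid parameter set with a
#' positive-definite `Sigma`, which is what makes unconstrained
#' quasi-Newton optimization possible.
#'
#' @param params An [mpt_params] object.
#' @param flat Named or ordered numeric vector as produced by
#'   `flatten_params`.
#' @param template An [mpt_params] object supplying the dimensions and
#'   masks.
#' @return `flatten_params`: a named numeric vector;
#'   `unflatten_params`: an [mpt_params] object.
#' @export
flatten_params <- function(params) {
  rand <- params$random
  R <- sum(rand)
  out <- c()
  nm <- c()
  if (any(!rand)) {
    out <- c(out, params$beta[!rand])
    nm <- c(nm, paste0("beta.", params$parameters[!rand]))
  }
  if (params$p > 0 && any(!rand)) {
    free <- which(params$gamma_mask)
    if (length(free)) {
      out <- c(out, params$gamma[free])
      idx <- arrayInd(free, dim(params$gamma))
      nm <- c(nm, paste0("gamma.", rownames(params$gamma)[idx[, 1]], ".", idx[, 2]))
    }
  }
  if (R > 0) {
    out <- c(out, params$mu)
    nm <- c(nm, paste0("mu.", params$parameters[rand]))
    if (params$p > 0) {
      free <- which(params$Gamma_mask)
      if (length(free)) {
        out <- c(out, params$Gamma[free])
        idx <- arrayInd(free, dim(params$Gamma))
        nm <- c(nm, paste0("Gamma.", rownames(params$Gamma)[idx[, 1]], ".", idx[, 2]))
      }
    }
    lc <- .logchol(params$Sigma)
    ij <- which(lower.tri(diag(R), diag = TRUE), arr.ind = TRUE)
    out <- c(out, lc)
    nm <- c(nm, paste0("L.", ij[, 1], ".", ij[, 2]))
  }
  stats::setNames(out, nm)
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(flat, template) {
  params <- template
  rand <- params$random
  R <- sum(rand)
  i <- 0L
  take <- function(n) {
    v <- flat[i + seq_len(n)]
    i <<- i + n
    v
  }
  if (any(!rand)) params$beta[!rand] <- take(sum(!rand))
  if (params$p > 0 && any(!rand)) {
    free <- which(params$gamma_mask)
    if (length(free)) params$gamma[free] <- take(length(free))
  }
  if (R > 0) {
    params$mu[] <- take(R)
    if (params$p > 0) {
      free <- which(params$Gamma_mask)
      if (length(free)) params$Gamma[free] <- take(length(free))
    }
    L <- .logchol_inv(take(R * (R + 1) / 2), R)
    params$Sigma <- L %*% t(L)
  }
  if (i != length(flat)) stop("flat parameter vector has wrong length", call. = FALSE)
  params
}

# number of free parameters, split by block (used for df accounting)
.free_param_counts <- function(params) {
  rand <- params$random
  R <- sum(rand)
  c(beta = sum(!rand),
    gamma = if (params$p > 0 && any(!rand)) sum(params$gamma_mask) else 0L,
    mu = R,
    Gamma = if (params$p > 0 && R > 0) sum(params$Gamma_mask) else 0L,
    Sigma = R * (R + 1) / 2)
}

# ---- person-level data ----------------------------------------------------

#' Person-level frequency data for an MPT model
#'
#' Wraps a participants-by-categories matrix of response frequencies
#' (columns named `tree.category`, matching the model's category layout)
#' plus optional person-level covariates.
#'
#' @param freq Integer matrix or data frame, one row per participant,
#'   one column per category.  Columns are mapped to model categories by
#'   name when the names match, otherwise by position (with a warning).
#' @param model An `mpt_model` defining the category layout.
#' @param covariates Optional numeric matrix/data frame of person-level
#'   covariates (one row per participant).
#' @param center Center covariates at their sample mean (default `TRUE`),
#'   so that `mu` and `beta` describe a person with average covariate
#'   values.
#' @return An object of class `mpt_data` with elements `freq` (T x J
#'   integer matrix), `covariates` (T x p matrix or `NULL`), and `totals`
#'   (T x K matrix of per-tree response totals).
#' @export
mpt_data <- function(freq, model, covariates = NULL, center = TRUE) {
  freq <- as.matrix(freq)
  J <- length(model$cat_labels)
  if (ncol(freq) != J) {
    stop(sprintf("frequency table has %d columns; model defines %d categories",
                 ncol(freq), J), call. = FALSE)
  }
  if (!is.null(colnames(freq)) && all(model$cat_labels %in% colnames(freq))) {
    freq <- freq[, model$cat_labels, drop = FALSE]
  } else {
    if (!is.null(colnames(freq)) &&
        !identical(colnames(freq), model$cat_labels)) {
      warning("frequency columns mapped by position, not by name")
    }
    colnames(freq) <- model$cat_labels
  }
  bad <- which(!is.finite(freq) | freq < 0 | freq != round(freq), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at row %d, column '%s'",
                 bad[1, 1], colnames(freq)[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(freq) <- "double"

  K <- length(model$trees)
  totals <- sapply(seq_len(K), function(k) {
    rowSums(freq[, model$cat_tree == k, drop = FALSE])
  })
  totals <- matrix(totals, nrow = nrow(freq), ncol = K,
                   dimnames = list(NULL, model$trees))

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != nrow(freq)) {
      stop("covariates must have one row per participant", call. = FALSE)
    }
    if (center) {
      covariates <- scale(covariates, center = TRUE, scale = FALSE)
      attr(covariates, "scaled:center") <- NULL
    }
  }
  structure(list(freq = freq, covariates = covariates, totals = totals),
            class = "mpt_data")
}

#' @export
print.mpt_data <- function(x, ...) {
  cat(sprintf("mpt_data: %d participants, %d categories%s\n",
              nrow(x$freq), ncol(x$freq),
              if (is.null(x$covariates)) "" else
                sprintf(", %d covariates", ncol(x$covariates))))
  invisible(x)
}

# one person's data as a light list (counts vector + covariates)
.person <- function(data, t) {
  list(n = data$freq[t, ], X = if (is.null(data$covariates)) NULL
       else data$covariates[t, ])
}

# log multinomial coefficients, one per person (vector over persons)
.log_multinom_coef <- function(model, freq) {
  K <- length(model$trees)
  out <- numeric(nrow(freq))
  for (k in seq_len(K)) {
    nk <- freq[, model$cat_tree == k, drop = FALSE]
    out <- out + lgamma(rowSums(nk) + 1) - rowSums(lgamma(nk + 1))
  }
  out
}
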