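# Simulation-study harness: relative bias, CI coverage, and convergence
# rate over a T x N x method grid, at configurable replication counts.

#' Relative bias of estimates against truth
#'
#' `100 * (mean(estimate) - truth) / truth` per parameter; parameters
#' with zero truth are undefined and reported as `NA`.
#'
#' @param estimates Replications x parameters matrix (or vector for one
#'   parameter).
#' @param truth Numeric vector of true values.
#' @return Named numeric vector of relative biases in percent.
#' @export
relative_bias <- function(estimates, truth) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1L)
  m <- colMeans(estimates)
  out <- ifelse(truth == 0, NA_real_, 100 * (m - truth) / truth)
  stats::setNames(out, colnames(estimates))
}

#' Wald confidence-interval coverage rate
#'
#' Share of replications whose interval `estimate +/- z * se` contains
#' the true value, in percent.
#'
#' @param estimates,std_errors Replications x parameters matrices.
#' @param truth Numeric vector of true values.
#' @param alpha CI level complement (default 0.05 for 95% intervals).
#' @return Named numeric vector of coverage rates in percent.
#' @export
coverage_rate <- function(estimates, std_errors, truth, alpha = 0.05) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1L)
  if (is.null(dim(std_errors))) std_errors <- matrix(std_errors, ncol = 1L)
  z <- stats::qnorm(1 - alpha / 2)
  hit <- sweep(estimates - z * std_errors, 2L, truth, "<=") &
    sweep(estimates + z * std_errors, 2L, truth, ">=")
  stats::setNames(100 * colMeans(hit), colnames(estimates))
}

# per-replication record of the reporting-scale quantities:
# probability-scale means (bias), link-scale means + SEs (coverage),
# natural-scale variances/covariances + delta-method SEs
.study_record <- function(fit) {
  link <- fit$settings$link
  rn <- fit$params$parameters[fit$params$random]
  mu <- fit$params$mu
  se <- fit$std_errors
  mu_se <- se[paste0("mu.", rn)]
  st <- fit$sigma_table
  R <- length(rn)
  ij <- which(lower.tri(diag(R), diag = TRUE), arr.ind = TRUE)
  is_var <- ij[, 1] == ij[, 2]
  list(converged = isTRUE(fit$converged),
       mu_prob = stats::setNames(link_inverse(mu, link), rn),
       mu_link = stats::setNames(unname(mu), rn),
       mu_se = stats::setNames(unname(mu_se), rn),
       var_est = stats::setNames(st$estimate[is_var], rn[ij[is_var, 1]]),
       var_se = stats::setNames(st$se[is_var], rn[ij[is_var, 1]]),
       cov_est = stats::setNames(st$estimate[!is_var], st$component[!is_var]),
       cov_se = stats::setNames(st$se[!is_var], st$component[!is_var]))
}

#' Run a bias/coverage/convergence simulation study
#'
#' For every cell of the `T_grid` x `N_grid` x `methods` design:
#' simulate data from the population, fit the model, and record
#' convergence (finite estimates, positive-definite covariance, defined
#' standard errors), relative bias, and 95% CI coverage, aggregated per
#' parameter group (means `mu`; variances `sigma2_b`; covariances
#' `sigma_bb`).  Mean parameters are compared on the probability scale
#' and their CIs on the link scale; (co)variances on the natural
#' link-scale covariance with delta-method standard errors.  Failed or
#' non-converged replications are excluded from bias and coverage but
#' counted in the convergence rate.  Replication seeds derive
#' deterministically from `seed`.
#'
#' @param population An `mpt_population`.
#' @param T_grid Integer vector of participant counts.
#' @param N_grid Named list of per-tree response-count vectors, e.g.
#'   `list("25" = c(20, 5))`.
#' @param methods List of back-end settings, each a list with `method`
#'   and `nodes` / `qmc_points`.
#' @param replications Replications per cell.
#' @param seed Master seed.
#' @param alpha CI level complement (default 0.05).
#' @param keep_records Keep the per-replication records (default TRUE).
#' @return An `mpt_study`: list with `table` (one row per cell x
#'   parameter group: relative bias, coverage, their Monte Carlo
#'   standard errors, and convergence rate) and, optionally, `records`.
#' @export
run_study <- function(population, T_grid, N_grid, methods,
                      replications = 10L, seed = 1L, alpha = 0.05,
                      keep_records = TRUE) {
  stopifnot(replications >= 1L)
  if (is.null(names(N_grid))) {
    names(N_grid) <- vapply(N_grid, function(x) as.character(sum(x)), "")
  }
  cells <- expand.grid(m = seq_along(methods), Ti = seq_along(T_grid),
                       Ni = seq_along(N_grid))
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, nrow(cells) * replications),
                  nrow(cells), replications)

  truth_mu_prob <- population$mu_prob
  truth_mu_link <- link_forward(population$mu_prob, population$link)
  S <- length(truth_mu_prob)
  ij <- which(lower.tri(diag(S), diag = TRUE), arr.ind = TRUE)
  is_var <- ij[, 1] == ij[, 2]
  vechS <- population$Sigma[lower.tri(population$Sigma, diag = TRUE)]
  truth_var <- vechS[is_var]
  truth_cov <- vechS[!is_var]

  rows <- list()
  all_records <- list()
  for (ci in seq_len(nrow(cells))) {
    mset <- methods[[cells$m[ci]]]
    Tv <- T_grid[cells$Ti[ci]]
    counts <- N_grid[[cells$Ni[ci]]]
    recs <- vector("list", replications)
    for (r in seq_len(replications)) {
      sim <- simulate_mpt(population, T = Tv, counts = counts,
                          seed = seeds[ci, r])
      fit <- tryCatch(
        fit_mpt(population$model, sim$data, link = population$link,
                method = mset$method,
                nodes = if (is.null(mset$nodes)) 4L else mset$nodes,
                qmc_points = if (is.null(mset$qmc_points)) 1000L
                else mset$qmc_points),
        error = function(e) NULL)
      recs[[r]] <- if (is.null(fit) || !isTRUE(fit$converged) ||
                       is.null(fit$sigma_table)) {
        list(converged = FALSE)
      } else {
        .study_record(fit)
      }
    }
    conv <- vapply(recs, function(x) isTRUE(x$converged), TRUE)
    ok <- which(conv)
    lab <- sprintf("%s-%s", mset$method,
                   if (identical(mset$method, "qmc"))
                     if (is.null(mset$qmc_points)) 1000L else mset$qmc_points
                   else if (is.null(mset$nodes)) 4L else mset$nodes)

    grp_row <- function(group, rb, rb_se, cov, cov_se) {
      data.frame(method = lab, T = Tv, N = names(N_grid)[cells$Ni[ci]],
                 group = group, rel_bias = rb, rel_bias_mc_se = rb_se,
                 coverage = cov, coverage_mc_se = cov_se,
                 convergence = mean(conv), n_converged = length(ok))
    }
    if (length(ok)) {
      get_mat <- function(field) {
        do.call(rbind, lapply(recs[ok], `[[`, field))
      }
      # per-replication group-averaged relative bias and coverage, so
      # Monte Carlo error bands are well-defined at small rep counts
      z <- stats::qnorm(1 - alpha / 2)
      grb <- function(est, truth) {
        dev <- sweep(sweep(est, 2L, truth, "-"), 2L, truth, "/") * 100
        rowMeans(dev[, truth != 0, drop = FALSE])
      }
      gcov <- function(est, se, truth) {
        hit <- sweep(est - z * se, 2L, truth, "<=") &
          sweep(est + z * se, 2L, truth, ">=")
        100 * rowMeans(hit)
      }
      mc <- function(x) stats::sd(x) / sqrt(length(x))

      b_mu <- grb(get_mat("mu_prob"), truth_mu_prob)
      c_mu <- gcov(get_mat("mu_link"), get_mat("mu_se"), truth_mu_link)
      b_v <- grb(get_mat("var_est"), truth_var)
      c_v <- gcov(get_mat("var_est"), get_mat("var_se"), truth_var)
      b_c <- grb(get_mat("cov_est"), truth_cov)
      c_c <- gcov(get_mat("cov_est"), get_mat("cov_se"), truth_cov)

      rows[[length(rows) + 1L]] <- rbind(
        grp_row("mu", mean(b_mu), mc(b_mu), mean(c_mu), mc(c_mu)),
        grp_row("sigma2_b", mean(b_v), mc(b_v), mean(c_v), mc(c_v)),
        grp_row("sigma_bb", mean(b_c), mc(b_c), mean(c_c), mc(c_c)))
    } else {
      rows[[length(rows) + 1L]] <- rbind(
        grp_row("mu", NA, NA, NA, NA),
        grp_row("sigma2_b", NA, NA, NA, NA),
        grp_row("sigma_bb", NA, NA, NA, NA))
    }
    if (keep_records) {
      all_records[[sprintf("%s_T%d_N%s", lab, Tv,
                           names(N_grid)[cells$Ni[ci]])]] <- recs
    }
  }
  structure(list(table = do.call(rbind, rows),
                 records = if (keep_records) all_records,
                 truth = list(mu_prob = truth_mu_prob,
                              mu_link = truth_mu_link,
                              Sigma = population$Sigma),
                 seed = seed, replications = replications),
            class = "mpt_study")
}

#' @export
print.mpt_study <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation study: %d replications per cell (seed %d)\n",
              x$replications, x$seed))
  tab <- x$table
  tab$rel_bias <- round(tab$rel_bias, digits)
  tab$coverage <- round(tab$coverage, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}
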