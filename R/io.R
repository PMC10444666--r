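# File readers/writers: frequency tables in delimited text, fit results
# as JSON.

#' Read a person-level frequency table
#'
#' Reads a delimited text file (comma, tab, or semicolon separated, with
#' a header) containing one row per participant and one integer column
#' per model category, named `tree.category`.  Columns are mapped to the
#' model's categories by name; if the names do not match, they are
#' mapped by position with a warning.  Remaining numeric columns named
#' in `covariate_names` become person-level covariates.
#'
#' @param path Path to the delimited file.
#' @param model An `mpt_model`.
#' @param covariate_names Optional character vector of covariate column
#'   names.
#' @param center Center covariates (see [mpt_data()]).
#' @return An [mpt_data] object.
#' @export
read_frequencies <- function(path, model, covariate_names = NULL,
                             center = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- model$cat_labels
  if (all(labels %in% names(df))) {
    freq <- as.matrix(df[, labels, drop = FALSE])
  } else {
    missing_cols <- setdiff(labels, names(df))
    id_like <- grepl("^(id|participant|subject)$", tolower(names(df)))
    cand <- names(df)[!id_like & !(names(df) %in% covariate_names)]
    if (length(cand) < length(labels)) {
      stop(sprintf("missing category column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    warning("category columns mapped by position, not by name")
    freq <- as.matrix(df[, cand[seq_along(labels)], drop = FALSE])
    colnames(freq) <- labels
  }
  covariates <- NULL
  if (length(covariate_names)) {
    miss <- setdiff(covariate_names, names(df))
    if (length(miss)) {
      stop(sprintf("missing covariate column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    covariates <- as.matrix(df[, covariate_names, drop = FALSE])
  }
  mpt_data(freq, model, covariates = covariates, center = center)
}

#' Write / read a fit result as JSON
#'
#' Serializes the estimates, standard errors, Wald intervals,
#' log-likelihood, information criteria, convergence diagnostics, and a
#' settings echo at full numeric precision, so that
#' `read_fit(write_fit(fit, path))` round-trips the estimates exactly.
#'
#' @param fit An `mpt_fit`.
#' @param path Output (input) file path.
#' @return `write_fit` returns `path` invisibly; `read_fit` returns the
#'   parsed list.
#' @export
write_fit <- function(fit, path) {
  est <- fit$flat_estimates
  se <- if (is.null(fit$std_errors)) rep(NA_real_, length(est)) else fit$std_errors
  ic <- information_criteria(fit)
  out <- list(
    package = "mptmarg",
    version = as.character(utils::packageVersion("mptmarg")),
    settings = fit$settings[c("link", "method", "nodes", "qmc_points", "random")],
    converged = fit$converged,
    messages = fit$messages,
    loglik = fit$loglik,
    n_obs = fit$n_obs,
    df = unname(ic["df"]),
    AIC = unname(ic["AIC"]),
    BIC = unname(ic["BIC"]),
    estimates = as.list(est),
    std_errors = as.list(se),
    ci_lower = as.list(est - 1.96 * se),
    ci_upper = as.list(est + 1.96 * se),
    sigma_table = fit$sigma_table
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
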