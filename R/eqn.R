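#' Parse an MPT model from EQN text
#'
#' Reads a multinomial-processing-tree model in the EQN text format used
#' throughout the MPT community: one branch per line, written as
#' `tree category term`, where `term` is a product of process-parameter
#' names and complement factors `(1-name)`, e.g. `pairs C14 c*(1-r)`.
#' Lines that share the same `(tree, category)` pair are branches of the
#' same category and their probabilities are summed.  A leading line
#' containing only the number of branch lines (the "count-first" EQN
#' dialect) is tolerated and ignored, as are blank lines and lines
#' starting with `#`.
#'
#' @param text Character scalar (possibly multi-line) or character vector
#'   of lines containing the EQN description.
#' @return An object of class `mpt_model`: a validated tree structure
#'   holding the parameter labels, the category systems, and the integer
#'   exponent counts with which each parameter and its complement enter
#'   each branch product.
#' @seealso [read_eqn()], [write_eqn()], [apply_restrictions()],
#'   [category_probability()]
#' @examples
#' m <- parse_eqn("
#'   t A p
#'   t B (1-p)
#' ")
#' category_probs(m, 0.3)
#' @export
parse_eqn <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  raw <- trimws(lines)
  keep <- nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "//")
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) && grepl("^[0-9]+$", lines[[1L]])) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(lines)) {
    stop("empty EQN model: no branch lines found", call. = FALSE)
  }

  n_br <- length(lines)
  trees_raw <- character(n_br)
  cats_raw <- character(n_br)
  terms <- vector("list", n_br)
  params <- character(0)

  for (b in seq_len(n_br)) {
    tok <- strsplit(lines[[b]], "[[:space:]]+")[[1L]]
    if (length(tok) < 3L) {
      stop(sprintf("EQN line %d is not of the form 'tree category term': %s",
                   lineno[b], lines[[b]]), call. = FALSE)
    }
    trees_raw[b] <- tok[1L]
    cats_raw[b] <- tok[2L]
    term <- gsub("[[:space:]]", "", paste(tok[-(1:2)], collapse = ""))
    factors <- strsplit(term, "*", fixed = TRUE)[[1L]]
    if (!length(factors) || any(!nzchar(factors)) ||
        grepl("^\\*|\\*$", term)) {
      stop(sprintf("EQN line %d has a malformed term: %s", lineno[b], term),
           call. = FALSE)
    }
    parsed <- lapply(factors, function(f) {
      if (grepl("^\\(1-[[:alpha:]][[:alnum:]_.]*\\)$", f)) {
        list(par = substr(f, 4L, nchar(f) - 1L), comp = TRUE)
      } else if (grepl("^1-[[:alpha:]][[:alnum:]_.]*$", f)) {
        list(par = substr(f, 3L, nchar(f)), comp = TRUE)
      } else if (grepl("^[[:alpha:]][[:alnum:]_.]*$", f)) {
        list(par = f, comp = FALSE)
      } else {
        stop(sprintf(
          "EQN line %d: cannot parse factor '%s' (expected a parameter name or (1-name))",
          lineno[b], f), call. = FALSE)
      }
    })
    terms[[b]] <- parsed
    params <- union(params, vapply(parsed, `[[`, "", "par"))
  }

  S <- length(params)
  A <- matrix(0L, n_br, S, dimnames = list(NULL, params))
  B <- matrix(0L, n_br, S, dimnames = list(NULL, params))
  for (b in seq_len(n_br)) {
    for (f in terms[[b]]) {
      if (f$comp) B[b, f$par] <- B[b, f$par] + 1L
      else A[b, f$par] <- A[b, f$par] + 1L
    }
  }

  key <- paste(trees_raw, cats_raw, sep = "\r")
  cat_id <- match(key, unique(key))               # order of first appearance
  u <- !duplicated(key)
  cat_tree_lab <- trees_raw[u]
  cat_lab <- cats_raw[u]
  trees <- unique(trees_raw)

  new_mpt_model(
    parameters = params,
    trees = trees,
    cat_tree = match(cat_tree_lab, trees),
    cat_names = cat_lab,
    A = A, B = B,
    branch_cat = cat_id,
    const_log = numeric(n_br)
  )
}

# internal constructor + validator
new_mpt_model <- function(parameters, trees, cat_tree, cat_names, A, B,
                          branch_cat, const_log) {
  m <- structure(
    list(parameters = parameters, trees = trees, cat_tree = cat_tree,
         cat_names = cat_names, A = A, B = B, branch_cat = branch_cat,
         const_log = const_log,
         cat_labels = paste(trees[cat_tree], cat_names, sep = ".")),
    class = "mpt_model")
  validate_mpt_model(m)
  m
}

validate_mpt_model <- function(m) {
  stopifnot(is.matrix(m$A), is.matrix(m$B),
            all(m$A >= 0), all(m$B >= 0),
            all(m$A == round(m$A)), all(m$B == round(m$B)),
            nrow(m$A) == length(m$branch_cat),
            length(m$const_log) == nrow(m$A))
  J <- length(m$cat_names)
  if (!all(seq_len(J) %in% m$branch_cat)) {
    stop("every category must have at least one branch", call. = FALSE)
  }
  for (k in seq_along(m$trees)) {
    labs <- m$cat_names[m$cat_tree == k]
    if (anyDuplicated(labs)) {
      stop(sprintf("duplicate category labels within tree '%s'", m$trees[k]),
           call. = FALSE)
    }
  }
  invisible(m)
}

#' @rdname parse_eqn
#' @param file Path to an EQN model file.
#' @export
read_eqn <- function(file) {
  parse_eqn(readLines(file, warn = FALSE))
}

#' Serialize an MPT model back to EQN text
#'
#' Writes one `tree category term` line per branch; repeated factors are
#' expanded so that re-parsing the output recovers the exact exponent
#' structure.  Branch constants introduced by fixed-value restrictions
#' cannot be represented in plain EQN and raise an error.
#'
#' @param model An `mpt_model`.
#' @param file Optional path; if `NULL` the text is returned invisibly.
#' @return The EQN lines, invisibly.
#' @export
write_eqn <- function(model, file = NULL) {
  if (any(model$const_log != 0)) {
    stop("model carries numeric branch constants (from fixed-value ",
         "restrictions) that EQN text cannot express", call. = FALSE)
  }
  lines <- vapply(seq_along(model$branch_cat), function(b) {
    comp <- rep(model$parameters, times = model$B[b, ])
    facs <- c(
      rep(model$parameters, times = model$A[b, ]),
      if (length(comp)) paste0("(1-", comp, ")")
    )
    if (!length(facs)) facs <- "1"   # empty product; not re-parseable, guard
    ci <- model$branch_cat[b]
    paste(model$trees[model$cat_tree[ci]], model$cat_names[ci],
          paste(facs, collapse = "*"))
  }, "")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.mpt_model <- function(x, ...) {
  cat(sprintf("MPT model: %d parameters (%s), %d trees, %d categories, %d branches\n",
              length(x$parameters), paste(x$parameters, collapse = ", "),
              length(x$trees), length(x$cat_names), nrow(x$A)))
  for (b in seq_along(x$branch_cat)) {
    ci <- x$branch_cat[b]
    comp <- rep(x$parameters, times = x$B[b, ])
    facs <- c(rep(x$parameters, times = x$A[b, ]),
              if (length(comp)) paste0("(1-", comp, ")"))
    term <- if (length(facs)) paste(facs, collapse = "*") else "1"
    if (x$const_log[b] != 0) {
      term <- paste0(sprintf("%.6g", exp(x$const_log[b])), "*", term)
    }
    cat(sprintf("  %-12s %-8s %s\n", x$trees[x$cat_tree[ci]],
                x$cat_names[ci], term))
  }
  invisible(x)
}

.check_theta <- function(model, theta) {
  S <- length(model$parameters)
  if (length(theta) != S) {
    stop(sprintf("theta must have length %d", S), call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 1)) {
    stop("theta must lie strictly inside the unit hypercube", call. = FALSE)
  }
  invisible(theta)
}

#' Branch and category probabilities
#'
#' `branch_probability()` evaluates the probability of a single
#' root-to-leaf branch, the product over parameters s of
#' `theta_s^a * (1-theta_s)^b` with the model's integer exponents.
#' `category_probability()` sums the branch probabilities of the branches
#' terminating in one category; `category_probs()` returns the full
#' vector of category probabilities (named `tree.category`), which sums
#' to one within each tree.
#'
#' Probabilities are evaluated in log space, so deep trees with large
#' exponents do not underflow.
#'
#' @param model An `mpt_model`.
#' @param k Tree (category-system) index.
#' @param j Category index within tree `k`.
#' @param i Branch index within category `j`.
#' @param theta Numeric vector of process-parameter values, strictly
#'   inside (0, 1), ordered as `model$parameters`.
#' @return A probability (or named probability vector for
#'   `category_probs`).
#' @export
branch_probability <- function(model, k, j, i, theta) {
  .check_theta(model, theta)
  cats_k <- which(model$cat_tree == k)
  if (!length(cats_k)) stop("tree index out of range", call. = FALSE)
  if (j < 1 || j > length(cats_k)) stop("category index out of range", call. = FALSE)
  br <- which(model$branch_cat == cats_k[j])
  if (i < 1 || i > length(br)) stop("branch index out of range", call. = FALSE)
  b <- br[i]
  exp(sum(model$A[b, ] * log(theta)) + sum(model$B[b, ] * log1p(-theta)) +
        model$const_log[b])
}

#' @rdname branch_probability
#' @export
category_probability <- function(model, k, j, theta) {
  .check_theta(model, theta)
  cats_k <- which(model$cat_tree == k)
  if (!length(cats_k)) stop("tree index out of range", call. = FALSE)
  if (j < 1 || j > length(cats_k)) stop("category index out of range", call. = FALSE)
  unname(category_probs(model, theta)[cats_k[j]])
}

#' @rdname branch_probability
#' @export
category_probs <- function(model, theta) {
  .check_theta(model, theta)
  p <- drop(.cat_prob_matrix(model, matrix(theta, nrow = 1L)))
  names(p) <- model$cat_labels
  p
}

# Vectorized category probabilities: Theta is an n x S matrix of
# parameter values (rows strictly inside (0,1) after clamping); returns
# an n x J matrix.  All branch products go through one pair of matrix
# multiplications in log space.
.cat_prob_matrix <- function(model, Theta) {
  Theta <- .clamp01(Theta)
  logPB <- log(Theta) %*% t(model$A) + log1p(-Theta) %*% t(model$B)
  logPB <- sweep(logPB, 2L, model$const_log, "+")
  J <- length(model$cat_names)
  M <- matrix(0, nrow(model$A), J)
  M[cbind(seq_along(model$branch_cat), model$branch_cat)] <- 1
  exp(logPB) %*% M
}

.clamp01 <- function(x, eps = 1e-12) {
  x[x < eps] <- eps
  x[x > 1 - eps] <- 1 - eps
  x
}

#' Apply parameter restrictions to an MPT model
#'
#' Equality restrictions (`"u = a"`) merge the subject parameter's
#' exponent counts onto the target parameter, reducing the number of free
#' process parameters; fixed-value restrictions (`"a = 0.85"`) remove the
#' parameter and fold the constant into the branch probabilities.
#' Equality chains are resolved transitively and must be acyclic.
#'
#' @param model An `mpt_model`.
#' @param restrictions Character vector of restrictions of the form
#'   `"par = target"` or `"par = value"`, or a list of such strings.
#' @return A new `mpt_model` with the restrictions applied.
#' @examples
#' pc <- parse_eqn(mptmarg_example("pair_clustering"))
#' pc3 <- apply_restrictions(pc, "u = a")
#' length(pc3$parameters)  # 3
#' @export
apply_restrictions <- function(model, restrictions) {
  if (!length(restrictions)) return(model)
  restrictions <- unlist(restrictions, use.names = FALSE)
  parts <- lapply(restrictions, function(r) {
    sp <- strsplit(gsub("[[:space:]]", "", r), "=", fixed = TRUE)[[1L]]
    if (length(sp) != 2L) {
      stop(sprintf("cannot parse restriction '%s'", r), call. = FALSE)
    }
    sp
  })
  subj <- vapply(parts, `[[`, "", 1L)
  targ <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(subj)) {
    stop("a parameter is restricted more than once", call. = FALSE)
  }
  unknown <- setdiff(subj, model$parameters)
  if (length(unknown)) {
    stop(sprintf("restriction subject not in model: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  is_num <- suppressWarnings(!is.na(as.numeric(targ)))
  # resolve equality chains u = a, a = g -> u points to g; detect cycles
  resolve <- function(s, seen = character(0)) {
    idx <- match(s, subj)
    if (is.na(idx) || is_num[idx]) return(s)
    if (s %in% seen) {
      stop("cyclic equality restriction chain", call. = FALSE)
    }
    resolve(targ[idx], c(seen, s))
  }

  A <- model$A
  B <- model$B
  const_log <- model$const_log
  drop_pars <- character(0)

  for (r in seq_along(subj)) {
    s <- subj[r]
    if (is_num[r]) {
      v <- as.numeric(targ[r])
      if (v < 0 || v > 1) {
        stop(sprintf("fixed value for '%s' outside [0, 1]", s), call. = FALSE)
      }
      la <- ifelse(A[, s] > 0, A[, s] * log(v), 0)      # 0*log(0) := 0
      lb <- ifelse(B[, s] > 0, B[, s] * log1p(-v), 0)
      const_log <- const_log + la + lb
    } else {
      tg <- resolve(targ[r])
      if (!(tg %in% model$parameters)) {
        stop(sprintf("restriction target '%s' is not a model parameter", tg),
             call. = FALSE)
      }
      if (identical(tg, s)) stop("cyclic equality restriction chain", call. = FALSE)
      if (!is.na(match(tg, subj)) && is_num[match(tg, subj)]) {
        # chain ends in a fixed value: fold the constant directly
        v <- as.numeric(targ[match(tg, subj)])
        la <- ifelse(A[, s] > 0, A[, s] * log(v), 0)
        lb <- ifelse(B[, s] > 0, B[, s] * log1p(-v), 0)
        const_log <- const_log + la + lb
      } else {
        A[, tg] <- A[, tg] + A[, s]
        B[, tg] <- B[, tg] + B[, s]
      }
    }
    drop_pars <- c(drop_pars, s)
  }

  keep <- setdiff(model$parameters, drop_pars)
  if (!length(keep)) {
    stop("restrictions remove every parameter from the model", call. = FALSE)
  }
  new_mpt_model(
    parameters = keep,
    trees = model$trees,
    cat_tree = model$cat_tree,
    cat_names = model$cat_names,
    A = A[, keep, drop = FALSE],
    B = B[, keep, drop = FALSE],
    branch_cat = model$branch_cat,
    const_log = const_log
  )
}

#' Built-in example model files
#'
#' Returns the text of a bundled EQN model.  `"pair_clustering"` is the
#' classic storage-retrieval model for free recall of semantically
#' related word pairs plus singletons: parameters `c` (cluster storage),
#' `r` (cluster retrieval), `u` (storage-retrieval of a non-clustered
#' pair word), and `a` (storage-retrieval of a singleton), with a
#' four-category tree for the pairs and a two-category tree for the
#' singletons.
#'
#' @param name Model name; currently only `"pair_clustering"`.
#' @return Character scalar of EQN text.
#' @export
mptmarg_example <- function(name = "pair_clustering") {
  name <- match.arg(name)
  paste(
    "# pair-clustering model: c r u a",
    "pairs C11 c*r",
    "pairs C12 (1-c)*u*u",
    "pairs C13 (1-c)*u*(1-u)",
    "pairs C13 (1-c)*(1-u)*u",
    "pairs C14 c*(1-r)",
    "pairs C14 (1-c)*(1-u)*(1-u)",
    "singletons C21 a",
    "singletons C22 (1-a)",
    sep = "\n")
}
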