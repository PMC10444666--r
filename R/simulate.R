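# Synthetic-data generator: draws person parameters from the
# latent-trait model and emits product-multinomial frequencies.

#' Default simulation population
#'
#' The pair-clustering population used for the bias/coverage
#' experiments: probability-scale parameter means
#' `(c, r, u, a) = (0.50, 0.40, 0.25, 0.15)` and link-scale covariance
#' \deqn{\Sigma = \begin{pmatrix} 0.50 & 0.08 & 0.04 & 0.00\\
#'   0.08 & 0.35 & 0.03 & 0.00\\ 0.04 & 0.03 & 0.20 & 0.07\\
#'   0.00 & 0.00 & 0.07 & 0.20 \end{pmatrix}}
#' (non-zero covariances correspond to correlations 0.30, 0.20, 0.10).
#' Responses are split roughly 80/20 between the pair and singleton
#' systems; the default per-person counts are 20 pairs and 5 singletons,
#' with 75 participants.  The link is probit (the latent-trait
#' convention); the means are interpreted on the probability scale and
#' transformed to link-scale means by the forward link, while `Sigma` is
#' link-scale.
#'
#' @param link `"probit"` (default) or `"logit"`.
#' @return An `mpt_population`: list with `model`, `link`, `mu_prob`,
#'   `Sigma`, `T`, and `counts` (per-tree response totals).
#' @export
default_population <- function(link = c("probit", "logit")) {
  link <- match.arg(link)
  Sigma <- matrix(c(0.50, 0.08, 0.04, 0.00,
                    0.08, 0.35, 0.03, 0.00,
                    0.04, 0.03, 0.20, 0.07,
                    0.00, 0.00, 0.07, 0.20), 4, 4, byrow = TRUE,
                  dimnames = list(c("c", "r", "u", "a"), c("c", "r", "u", "a")))
  mpt_population(model = parse_eqn(mptmarg_example("pair_clustering")),
                 mu_prob = c(c = 0.50, r = 0.40, u = 0.25, a = 0.15),
                 Sigma = Sigma, T = 75L,
                 counts = c(pairs = 20L, singletons = 5L), link = link)
}

#' Simulation population specification
#'
#' @param model An `mpt_model`; all of its parameters are treated as
#'   random (person-varying).
#' @param mu_prob Probability-scale mean of every process parameter,
#'   strictly inside (0, 1); link-scale means are obtained through the
#'   forward link.
#' @param Sigma Link-scale covariance of the person effects (positive
#'   definite).
#' @param T Default number of participants.
#' @param counts Named or ordered vector of per-tree response totals per
#'   participant.
#' @param link `"probit"` or `"logit"`.
#' @return An object of class `mpt_population`.
#' @export
mpt_population <- function(model, mu_prob, Sigma, T = 75L, counts,
                           link = c("probit", "logit")) {
  link <- match.arg(link)
  S <- length(model$parameters)
  stopifnot(length(mu_prob) == S, all(mu_prob > 0 & mu_prob < 1))
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == S, ncol(Sigma) == S)
  .check_pd(Sigma, "Sigma")
  counts <- rep_len(counts, length(model$trees))
  stopifnot(all(counts > 0))
  structure(list(model = model, mu_prob = mu_prob, Sigma = Sigma,
                 T = as.integer(T), counts = counts, link = link),
            class = "mpt_population")
}

#' Simulate person-level MPT frequencies
#'
#' Draws each participant's link-scale person parameters from
#' `MVN(link_forward(mu_prob), Sigma)`, maps them through the inverse
#' link to process probabilities, and draws each category system's
#' counts from a multinomial with the model-implied category
#' probabilities.  Fully reproducible from `seed`.
#'
#' @param population An `mpt_population` (see [default_population()]).
#' @param T Number of participants (default from the population).
#' @param counts Per-tree response totals (default from the population).
#' @param seed Integer seed.
#' @return List with `data` (an [mpt_data]), `b` (the simulated T x S
#'   link-scale person effects), and `truth` (list with `mu` link-scale
#'   means, `mu_prob`, and `Sigma`).
#' @export
simulate_mpt <- function(population, T = population$T,
                         counts = population$counts, seed = NULL) {
  model <- population$model
  S <- length(model$parameters)
  mu <- link_forward(population$mu_prob, population$link)
  if (!is.null(seed)) set.seed(seed)
  b <- MASS::mvrnorm(T, mu = mu, Sigma = population$Sigma)
  b <- matrix(b, T, S)
  Theta <- .clamp01(if (population$link == "probit") stats::pnorm(b)
                    else stats::plogis(b))
  P <- .cat_prob_matrix(model, Theta)
  K <- length(model$trees)
  counts <- rep_len(counts, K)
  freq <- matrix(0, T, length(model$cat_labels),
                 dimnames = list(NULL, model$cat_labels))
  for (k in seq_len(K)) {
    jj <- which(model$cat_tree == k)
    for (t in seq_len(T)) {
      freq[t, jj] <- stats::rmultinom(1L, counts[k], P[t, jj])
    }
  }
  list(data = mpt_data(freq, model),
       b = b,
       truth = list(mu = mu, mu_prob = population$mu_prob,
                    Sigma = population$Sigma, link = population$link,
                    counts = counts, T = T))
}
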