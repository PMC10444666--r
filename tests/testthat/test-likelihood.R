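test_that("person_theta maps random effects and covariates correctly", {
  m <- pc_model()
  pr <- mpt_params(m)                    # all random, probit
  expect_equal(unname(person_theta(pr, rep(0, 4), link = "probit")),
               rep(0.5, 4))

  # one fixed parameter with beta = 0, gamma = 1, X = 2 under logit
  pr2 <- mpt_params(m, random = c("c", "r", "u"), beta = c(a = 0),
                    p = 1L, gamma = matrix(1, 1, 1))
  th <- person_theta(pr2, c(0, 0, 0), X = 2, link = "logit")
  expect_equal(unname(th["a"]), 1 / (1 + exp(-2)), tolerance = 1e-4)

  # zeroing a Gamma row leaves theta untouched by X (theta depends on b
  # only for random parameters)
  pr3 <- mpt_params(m, p = 1L, Gamma = matrix(c(0, 1, 1, 1), 4, 1))
  b <- c(0.3, -0.2, 0.1, 0)
  expect_equal(person_theta(pr3, b, X = 5), person_theta(pr3, b, X = -5))
})

test_that("conditional log-likelihood equals the product-multinomial oracle", {
  m <- pc_model()
  pr <- mpt_params(m)
  th <- c(0.5, 0.4, 0.25, 0.15)
  b <- qnorm(th)
  person <- list(n = c(2, 0, 1, 7, 1, 4))
  P <- category_probs(m, th)
  oracle <- dmultinom(c(2, 0, 1, 7), prob = P[1:4], log = TRUE) +
    dmultinom(c(1, 4), prob = P[5:6], log = TRUE)
  expect_equal(conditional_loglik(m, pr, b, person, "probit"), oracle,
               tolerance = 1e-10)

  # certain outcome after fixing a = 1: probability one, log-lik zero
  mf <- apply_restrictions(m, "a = 1")
  pr0 <- mpt_params(mf, random = character(0))
  expect_equal(conditional_loglik(mf, pr0, numeric(0),
                                  list(n = c(0, 0, 0, 0, 5, 0)), "probit"), 0)

  # doubling the counts doubles the non-coefficient part
  p1 <- list(n = c(3, 1, 2, 4, 2, 3))
  p2 <- list(n = 2 * p1$n)
  coef1 <- sum(lgamma(sum(p1$n[1:4]) + 1) - sum(lgamma(p1$n[1:4] + 1)),
               lgamma(sum(p1$n[5:6]) + 1) - sum(lgamma(p1$n[5:6] + 1)))
  coef2 <- sum(lgamma(sum(p2$n[1:4]) + 1) - sum(lgamma(p2$n[1:4] + 1)),
               lgamma(sum(p2$n[5:6]) + 1) - sum(lgamma(p2$n[5:6] + 1)))
  l1 <- conditional_loglik(m, pr, b, p1, "probit") - coef1
  l2 <- conditional_loglik(m, pr, b, p2, "probit") - coef2
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
})

test_that("joint log-density decomposes into its two addends", {
  bd <- bern_data()
  person <- list(n = bd$data$freq[3, ])
  b <- 0.4
  cl <- conditional_loglik(bd$model, bd$params, b, person, "probit")
  jl <- joint_logdensity(bd$model, bd$params, b, person, "probit")
  gauss <- dnorm(b, bd$params$mu, sqrt(bd$params$Sigma[1, 1]), log = TRUE)
  expect_equal(jl, cl + gauss, tolerance = 1e-12)

  # R = 1, Sigma = 1, b at the mean: Gaussian addend is log(1/sqrt(2 pi))
  pr1 <- mpt_params(bd$model, mu = 0.2, Sigma = matrix(1, 1, 1))
  expect_equal(joint_logdensity(bd$model, pr1, 0.2, person, "probit") -
                 conditional_loglik(bd$model, pr1, 0.2, person, "probit"),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # with no data the joint density decreases monotonically in |b - mu|
  empty <- list(n = c(0, 0))
  j0 <- joint_logdensity(bd$model, bd$params, as.numeric(bd$params$mu),
                         empty, "probit")
  j1 <- joint_logdensity(bd$model, bd$params, bd$params$mu + 1, empty, "probit")
  j2 <- joint_logdensity(bd$model, bd$params, bd$params$mu + 2, empty, "probit")
  expect_true(j0 > j1 && j1 > j2)
})

test_that("analytic scores match finite differences across models and links", {
  m <- pc_model()
  set.seed(14)
  sim <- small_pc_data(T = 5, seed = 77)
  X <- matrix(rnorm(10), 5, 2)
  dat <- mpt_data(sim$data$freq, m, covariates = X)

  configs <- list(
    list(pr = mpt_params(m, mu = c(0.1, -0.3, -0.5, -1),
                         Sigma = default_population()$Sigma), link = "probit"),
    list(pr = mpt_params(m, random = c("c", "u"), beta = c(r = -0.4, a = -1.1),
                         mu = c(0, -0.7),
                         Sigma = matrix(c(0.5, 0.1, 0.1, 0.3), 2), p = 2L,
                         gamma = matrix(rnorm(4, 0, 0.3), 2, 2),
                         Gamma = matrix(rnorm(4, 0, 0.3), 2, 2)),
         link = "logit")
  )
  for (cf in configs) {
    pr <- cf$pr
    R <- sum(pr$random)
    for (rep in 1:10) {
      t <- sample(5, 1)
      person <- list(n = dat$freq[t, ],
                     X = if (pr$p > 0) dat$covariates[t, ] else NULL)
      b <- rnorm(R, 0, 0.8)
      sc <- score_components(m, pr, b, person, cf$link)
      flat <- flatten_params(pr)
      fd <- vapply(seq_along(flat), function(j) {
        h <- 1e-6 * (1 + abs(flat[j]))
        up <- flat; up[j] <- up[j] + h
        dn <- flat; dn[j] <- dn[j] - h
        (joint_logdensity(m, unflatten_params(up, pr), b, person, cf$link) -
           joint_logdensity(m, unflatten_params(dn, pr), b, person, cf$link)) /
          (2 * h)
      }, 0)
      expect_equal(unname(sc$flat), fd, tolerance = 1e-5)
      fdb <- vapply(seq_len(R), function(l) {
        e <- numeric(R); e[l] <- 1e-6
        (joint_logdensity(m, pr, b + e, person, cf$link) -
           joint_logdensity(m, pr, b - e, person, cf$link)) / 2e-6
      }, 0)
      expect_equal(unname(sc$b), fdb, tolerance = 1e-5)
    }
  }
})

test_that("the flat parameter map is a bijection preserving positive definiteness", {
  m <- pc_model()
  set.seed(21)
  for (i in 1:20) {
    A <- matrix(rnorm(16, 0, 0.4), 4)
    pr <- mpt_params(m, mu = rnorm(4), Sigma = crossprod(A) + diag(0.05, 4))
    flat <- flatten_params(pr)
    pr2 <- unflatten_params(flat, pr)
    expect_equal(flatten_params(pr2), flat, tolerance = 1e-12)
    expect_equal(pr2$Sigma, pr$Sigma, tolerance = 1e-10)
    # arbitrary flat vectors always decode to a positive-definite Sigma
    v <- rnorm(length(flat), 0, 2)
    expect_silent(chol(unflatten_params(v, pr)$Sigma))
  }
})
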