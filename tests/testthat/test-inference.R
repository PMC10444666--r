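test_that("likelihood-ratio arithmetic and chi-square quantiles are correct", {
  r <- list(flat_estimates = numeric(3), loglik = -105)
  u <- list(flat_estimates = numeric(5), loglik = -100)
  lr <- lr_test(r, u)
  expect_equal(lr$statistic, 10)
  expect_identical(lr$df, 2L)
  expect_equal(lr$p_value, pchisq(10, 2, lower.tail = FALSE))

  # the 0.95 chi-square quantile at df = 19 is 30.14
  u19 <- list(flat_estimates = numeric(22), loglik = -100)
  r19 <- list(flat_estimates = numeric(3), loglik = -104.51)
  expect_equal(lr_test(r19, u19)$crit_05, 30.14, tolerance = 0.01)

  # LR = 0 gives p = 1; a better-fitting restricted model warns
  expect_equal(lr_test(list(flat_estimates = 1:2, loglik = -50),
                       list(flat_estimates = 1:4, loglik = -50))$p_value, 1)
  expect_warning(lr_test(list(flat_estimates = 1:2, loglik = -49),
                         list(flat_estimates = 1:4, loglik = -50)),
                 "optimizer failure")
  expect_error(lr_test(r, r), "identical")
})

test_that("information criteria implement the penalty bookkeeping", {
  f <- list(flat_estimates = numeric(5), loglik = -100, n_obs = 200)
  ic <- information_criteria(f)
  expect_equal(unname(ic["AIC"]), 210)
  expect_equal(unname(ic["BIC"]), 200 + log(200) * 5)

  # pair-clustering with all four parameters random and no covariates:
  # df = 4 means + 10 covariance parameters = 14
  pop <- default_population()
  sim <- simulate_mpt(pop, T = 10, counts = c(20, 5), seed = 91)
  fit <- fit_mpt(pop$model, sim$data, method = "laplace", se = "none")
  expect_identical(unname(information_criteria(fit)["df"]), 14)

  # one extra free weight raises the AIC penalty by exactly 2
  f6 <- list(flat_estimates = numeric(6), loglik = -100, n_obs = 200)
  expect_equal(information_criteria(f6)["AIC"] - ic["AIC"], c(AIC = 2))
})

test_that("LR statistics are chi-square calibrated under a true restriction", {
  # fixed-effects two-Bernoulli model with p = q in truth
  m <- bern2_model()
  mr <- apply_restrictions(m, "q = p")
  set.seed(99)
  lrs <- replicate(25, {
    y1 <- rbinom(20, 15, 0.6)
    y2 <- rbinom(20, 10, 0.6)
    freq <- cbind(y1, 15 - y1, y2, 10 - y2)
    colnames(freq) <- m$cat_labels
    fu <- fit_mpt(m, mpt_data(freq, m), random = character(0),
                  method = "laplace", se = "none")
    fr <- fit_mpt(mr, mpt_data(freq, mr), random = character(0),
                  method = "laplace", se = "none")
    lr_test(fr, fu)$statistic
  })
  # mean of a chi-square(1) is 1; allow generous Monte Carlo slack
  expect_lt(abs(mean(lrs) - 1), 3 * sqrt(2 / 25))
  expect_true(all(lrs > -1e-6))
})

test_that("random-effect predictors shrink and match a posterior-mean oracle", {
  bd <- bern_data(T = 25, N = 20, seed = 103)
  # append an empty person: both estimators must return the prior mean
  freq <- rbind(bd$data$freq, c(0, 0))
  dat <- mpt_data(freq, bd$model)
  fit <- fit_mpt(bd$model, dat, method = "aghq", nodes = 15)
  expect_true(fit$converged)
  eb <- predict_random_effects(fit, "empirical_bayes")
  md <- predict_random_effects(fit, "mode")
  expect_identical(dim(eb), c(26L, 1L))
  expect_equal(unname(eb[26, 1]), unname(fit$params$mu), tolerance = 1e-6)
  expect_equal(unname(md[26, 1]), unname(fit$params$mu), tolerance = 1e-6)

  # trapezoid oracle for the posterior mean of each person
  mu <- unname(fit$params$mu)
  s <- sqrt(fit$params$Sigma[1, 1])
  g <- seq(mu - 9 * s, mu + 9 * s, length.out = 8001)
  for (t in c(1, 7, 19)) {
    f <- vapply(g, function(b) {
      exp(joint_logdensity(bd$model, fit$params, b,
                           list(n = freq[t, ]), "probit"))
    }, 0)
    oracle <- sum(g * f) / sum(f)
    expect_equal(eb[t, 1], oracle, tolerance = 1e-3)
  }

  # shrinkage: empirical Bayes lies between the prior mean and the
  # person-level ML estimate on the link scale
  y <- freq[1:25, 1]
  ml_link <- qnorm(pmin(pmax(y / 20, 0.02), 0.98))
  expect_true(all(abs(eb[1:25, 1] - mu) <= abs(ml_link - mu) + 1e-6))
})
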