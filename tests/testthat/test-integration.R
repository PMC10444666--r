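test_that("Halton points follow the radical-inverse construction", {
  expect_equal(drop(halton_points(1, 3)), c(1 / 2, 1 / 4, 3 / 4))
  expect_equal(drop(halton_points(2, 1)), c(1 / 2, 1 / 3))
  H <- halton_points(3, 500)
  expect_true(all(H > 0 & H < 1))
  expect_identical(halton_points(3, 500), H)   # deterministic
  expect_error(halton_points(26, 10), "between")
})

test_that("modes and curvature behave correctly for empty and regular persons", {
  bd <- bern_data(T = 10)
  m <- bd$model
  # append a person with no recorded responses
  freq <- rbind(bd$data$freq, c(0, 0))
  dat <- mpt_data(freq, m)
  ms <- find_modes(m, bd$params, dat, "probit")
  expect_lt(max(ms$grad_norm), 1e-8)
  # empty person: mode at the prior mean, curvature Sigma
  expect_equal(ms$modes[11, 1], unname(bd$params$mu[1]), tolerance = 1e-8)
  expect_equal(ms$chol[[11]] %*% t(ms$chol[[11]]), bd$params$Sigma,
               tolerance = 1e-6)
  # a large all-success person has a mode strictly above the prior mean
  freq2 <- rbind(bd$data$freq, c(25, 0))
  ms2 <- find_modes(m, bd$params, mpt_data(freq2, m), "probit")
  expect_gt(ms2$modes[11, 1], bd$params$mu[1])
})

test_that("analytic mode curvature matches finite differences of the score", {
  pop <- default_population()
  sim <- simulate_mpt(pop, T = 6, counts = c(20, 5), seed = 15)
  pr <- mpt_params(pop$model, mu = qnorm(pop$mu_prob), Sigma = pop$Sigma)
  pre <- mptmarg:::.fit_pre(pop$model, pr, sim$data, "probit")
  set.seed(2)
  B <- matrix(rnorm(24, 0, 0.6), 6, 4)
  Ha <- mptmarg:::.stack_hess(pre, B)
  Hf <- mptmarg:::.stack_hess_fd(pre, B)
  for (t in 1:6) {
    expect_equal(Ha[[t]], Hf[[t]], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("AGHQ with one node collapses to the Laplace approximation", {
  pop <- default_population()
  sim <- simulate_mpt(pop, T = 8, counts = c(20, 5), seed = 31)
  pr <- mpt_params(pop$model, mu = qnorm(pop$mu_prob), Sigma = pop$Sigma)
  lap <- marginal_loglik(pop$model, pr, sim$data, method = "laplace")
  ag1 <- marginal_loglik(pop$model, pr, sim$data, method = "aghq", nodes = 1)
  expect_equal(ag1$per_person, lap$per_person, tolerance = 1e-13)
})

test_that("one-dimensional marginals match a dense quadrature oracle", {
  bd <- bern_data(T = 6, N = 30, seed = 19)
  oracle <- vapply(seq_len(6), function(t) {
    simpson_marginal_1d(bd$model, bd$params, list(n = bd$data$freq[t, ]))
  }, 0)
  ag <- marginal_loglik(bd$model, bd$params, bd$data, method = "aghq",
                        nodes = 15)
  qm <- marginal_loglik(bd$model, bd$params, bd$data, method = "qmc",
                        qmc_points = 4096)
  la <- marginal_loglik(bd$model, bd$params, bd$data, method = "laplace")
  expect_equal(ag$per_person, oracle, tolerance = 1e-8)
  expect_lt(abs(qm$total - sum(oracle)), 1e-3)
  expect_lt(abs(la$total - sum(oracle)), 5e-2)  # Laplace is the crude one
})

test_that("two-dimensional marginals match a dense trapezoid oracle", {
  m <- bern2_model()
  pr <- mpt_params(m, mu = c(0, -0.5),
                   Sigma = matrix(c(0.5, 0.15, 0.15, 0.4), 2))
  set.seed(23)
  b <- MASS::mvrnorm(4, c(0, -0.5), pr$Sigma)
  freq <- cbind(rbinom(4, 20, pnorm(b[, 1])), 0,
                rbinom(4, 10, pnorm(b[, 2])), 0)
  freq[, 2] <- 20 - freq[, 1]
  freq[, 4] <- 10 - freq[, 3]
  colnames(freq) <- m$cat_labels
  dat <- mpt_data(freq, m)
  oracle <- vapply(seq_len(4), function(t) {
    trapezoid_marginal_2d(m, pr, list(n = freq[t, ]))
  }, 0)
  ag <- marginal_loglik(m, pr, dat, method = "aghq", nodes = 10)
  qm <- marginal_loglik(m, pr, dat, method = "qmc", qmc_points = 4096)
  expect_lt(abs(ag$total - sum(oracle)), 1e-3)
  expect_lt(abs(qm$total - sum(oracle)), 1e-3)
  expect_lt(abs(ag$total - qm$total), 1e-3)
})

test_that("AGHQ values converge monotonically in the node count", {
  bd <- bern_data(T = 10, N = 20, seed = 29)
  vals <- vapply(c(2, 4, 6, 8, 10), function(M) {
    marginal_loglik(bd$model, bd$params, bd$data, method = "aghq",
                    nodes = M)$total
  }, 0)
  gaps <- abs(diff(vals))
  expect_true(all(diff(gaps) < 0))
})

test_that("all back ends are invariant to permuting persons", {
  pop <- default_population()
  sim <- simulate_mpt(pop, T = 9, counts = c(20, 5), seed = 37)
  pr <- mpt_params(pop$model, mu = qnorm(pop$mu_prob), Sigma = pop$Sigma)
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  datp <- mpt_data(sim$data$freq[perm, ], pop$model)
  for (meth in c("laplace", "aghq", "qmc")) {
    a <- marginal_loglik(pop$model, pr, sim$data, method = meth, nodes = 3,
                         qmc_points = 256)
    b <- marginal_loglik(pop$model, pr, datp, method = meth, nodes = 3,
                         qmc_points = 256)
    expect_equal(b$per_person, a$per_person[perm], tolerance = 1e-9)
  }
})

test_that("the AGHQ node budget guard triggers and the grid is a full tensor product", {
  pop <- default_population()
  sim <- simulate_mpt(pop, T = 2, counts = c(20, 5), seed = 3)
  pr <- mpt_params(pop$model, mu = qnorm(pop$mu_prob), Sigma = pop$Sigma)
  expect_error(
    marginal_loglik(pop$model, pr, sim$data, method = "aghq", nodes = 40),
    "qmc")
  expect_identical(nrow(mptmarg:::.node_scheme("aghq", 4, 4, 0)$Z), 256L)
  expect_identical(nrow(mptmarg:::.node_scheme("aghq", 4, 3, 0)$Z), 81L)
})
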