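test_that("a fixed-effects-only fit matches a direct simplex-optimization oracle", {
  pop <- default_population()
  sim <- simulate_mpt(pop, T = 15, counts = c(20, 5), seed = 55)
  m <- pop$model
  fit <- fit_mpt(m, sim$data, random = character(0), method = "laplace")
  expect_true(fit$converged)
  theta_fit <- link_inverse(fit$params$beta, "probit")

  # independent oracle: Nelder-Mead on the probability scale over the
  # pooled multinomial likelihood
  n_tot <- colSums(sim$data$freq)
  nll <- function(th) {
    if (any(th <= 1e-6 | th >= 1 - 1e-6)) return(1e10)
    p <- numeric(6)
    th <- setNames(th, m$parameters)
    for (j in 1:4) p[j] <- category_probability(m, 1, j, th)
    for (j in 1:2) p[4 + j] <- category_probability(m, 2, j, th)
    -sum(n_tot * log(p))
  }
  orc <- optim(rep(0.4, 4), nll,
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(theta_fit), orc$par, tolerance = 1e-5)
})

test_that("restarting at the optimum is a fixed point", {
  bd <- bern_data(T = 25, N = 20, seed = 61)
  fit <- fit_mpt(bd$model, bd$data, method = "aghq", nodes = 10)
  expect_true(fit$converged)
  fit2 <- fit_mpt(bd$model, bd$data, method = "aghq", nodes = 10,
                  start = fit$params)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(fit2$flat_estimates, fit$flat_estimates, tolerance = 1e-4)
})

test_that("the reported optimum has a small scaled marginal gradient", {
  bd <- bern_data(T = 25, N = 20, seed = 61)
  fit <- fit_mpt(bd$model, bd$data, method = "aghq", nodes = 15)
  expect_true(fit$converged)
  expect_lt(fit$grad_scaled, 1e-4)
  # with ample quadrature nodes the raw gradient is also genuinely small
  expect_lt(max(abs(fit$gradient)), 1e-2)
})

test_that("fitting is invariant to the order of persons", {
  pop <- default_population()
  sim <- simulate_mpt(pop, T = 20, counts = c(20, 5), seed = 67)
  perm <- sample(20)
  f1 <- fit_mpt(pop$model, sim$data, method = "laplace", se = "none")
  f2 <- fit_mpt(pop$model, mpt_data(sim$data$freq[perm, ], pop$model),
                method = "laplace", se = "none")
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f2$flat_estimates, f1$flat_estimates, tolerance = 1e-3)
})

test_that("the optimum improves on the starting point", {
  bd <- bern_data(T = 20, N = 15, seed = 71)
  start <- mpt_params(bd$model, mu = 0.8, Sigma = matrix(0.1, 1, 1))
  fit <- fit_mpt(bd$model, bd$data, method = "aghq", nodes = 10,
                 start = start)
  ll_start <- marginal_loglik(bd$model, start, bd$data, method = "aghq",
                              nodes = 10)$total
  expect_gte(fit$loglik, ll_start)
})

test_that("duplicating every person shrinks standard errors by about 1/sqrt(2)", {
  bd <- bern_data(T = 40, N = 25, seed = 73)
  f1 <- fit_mpt(bd$model, bd$data, method = "aghq", nodes = 10)
  d2 <- mpt_data(rbind(bd$data$freq, bd$data$freq), bd$model)
  f2 <- fit_mpt(bd$model, d2, method = "aghq", nodes = 10)
  expect_true(f1$converged && f2$converged)
  ratio <- f2$std_errors / f1$std_errors
  expect_equal(unname(ratio), rep(1 / sqrt(2), length(ratio)),
               tolerance = 0.07)
})

test_that("finite-difference and exact standard errors agree", {
  m <- bern2_model()
  pr <- mpt_params(m, mu = c(0, -0.5),
                   Sigma = matrix(c(0.5, 0.15, 0.15, 0.4), 2))
  set.seed(77)
  b <- MASS::mvrnorm(30, c(0, -0.5), pr$Sigma)
  freq <- cbind(rbinom(30, 25, pnorm(b[, 1])), 0,
                rbinom(30, 15, pnorm(b[, 2])), 0)
  freq[, 2] <- 25 - freq[, 1]
  freq[, 4] <- 15 - freq[, 3]
  colnames(freq) <- m$cat_labels
  fit <- fit_mpt(m, mpt_data(freq, m), method = "aghq", nodes = 8)
  expect_true(fit$converged)
  fe <- standard_errors(fit, "exact")
  expect_equal(unname(fe$std_errors / fit$std_errors),
               rep(1, length(fit$std_errors)), tolerance = 0.02)
})

test_that("a non-identified model is flagged through undefined standard errors", {
  # p and q enter every category only through their product pq
  m <- parse_eqn("t A p*q\nt B p*(1-q)\nt B (1-p)*q\nt B (1-p)*(1-q)")
  set.seed(5)
  y <- rbinom(25, 30, 0.2)
  freq <- cbind(y, 30 - y)
  colnames(freq) <- m$cat_labels
  fit <- fit_mpt(m, mpt_data(freq, m), random = character(0),
                 method = "laplace")
  expect_false(fit$converged)
  expect_true(any(grepl("standard errors", fit$messages)) ||
                any(!is.finite(fit$std_errors)))
})
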