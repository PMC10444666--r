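# Shared fixtures: models, small simulated datasets, and brute-force
# integration oracles.  Everything is generated in code.

pc_model <- function() parse_eqn(mptmarg_example("pair_clustering"))

# one-tree Bernoulli model with a single process parameter
bern_model <- function() parse_eqn("t A p\nt B (1-p)")

# two independent Bernoulli trees (R = 2 test bed)
bern2_model <- function() {
  parse_eqn("t1 A p\nt1 B (1-p)\nt2 C q\nt2 D (1-q)")
}

# Simpson-rule oracle for a one-dimensional marginal likelihood:
# integrates exp(joint_logdensity) over b on [mu - 10 s, mu + 10 s]
simpson_marginal_1d <- function(model, params, person, link = "probit",
                                n = 20001) {
  mu <- unname(params$mu[1])
  s <- sqrt(params$Sigma[1, 1])
  g <- seq(mu - 10 * s, mu + 10 * s, length.out = n)
  f <- vapply(g, function(b) {
    exp(joint_logdensity(model, params, b, person, link))
  }, 0)
  h <- g[2] - g[1]
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  log(h / 3 * sum(w * f))
}

# dense trapezoid oracle for a two-dimensional marginal likelihood
trapezoid_marginal_2d <- function(model, params, person, link = "probit",
                                  n = 161, width = 7) {
  mu <- params$mu
  s <- sqrt(diag(params$Sigma))
  g1 <- seq(mu[1] - width * s[1], mu[1] + width * s[1], length.out = n)
  g2 <- seq(mu[2] - width * s[2], mu[2] + width * s[2], length.out = n)
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      f[i, j] <- exp(joint_logdensity(model, params, c(g1[i], g2[j]),
                                      person, link))
    }
  }
  w1 <- c(0.5, rep(1, n - 2), 0.5) * (g1[2] - g1[1])
  w2 <- c(0.5, rep(1, n - 2), 0.5) * (g2[2] - g2[1])
  log(drop(t(w1) %*% f %*% w2))
}

# small pair-clustering dataset from the default population
small_pc_data <- function(T = 12, counts = c(20, 5), seed = 101) {
  simulate_mpt(default_population(), T = T, counts = counts, seed = seed)
}

# Bernoulli-tree dataset with known person effects
bern_data <- function(T = 30, N = 25, mu = -0.25, s2 = 0.35, seed = 7) {
  set.seed(seed)
  b <- rnorm(T, mu, sqrt(s2))
  y <- rbinom(T, N, pnorm(b))
  m <- bern_model()
  freq <- cbind(y, N - y)
  colnames(freq) <- m$cat_labels
  list(model = m, data = mpt_data(freq, m), b = b,
       params = mpt_params(m, mu = mu, Sigma = matrix(s2, 1, 1)))
}
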