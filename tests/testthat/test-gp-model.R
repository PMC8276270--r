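test_that("kernel matrix matches its closed form and stays PSD", {
  K <- kernel_matrix(c(1, 2, 4), alpha = 1, rho = 1, sigma = 0)
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K[1, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(K[1, 3], exp(-4.5), tolerance = 1e-12)

  K2 <- kernel_matrix(c(0, 2), alpha = 1.5, rho = 0.7, sigma = 0.3)
  expect_equal(diag(K2), rep(1.5^2 + 0.3^2, 2))

  # decay limit: separations of 100 rho are numerically zero
  K3 <- kernel_matrix(c(0, 100), alpha = 2, rho = 1, sigma = 1)
  expect_lt(K3[1, 2], 1e-300)

  expect_error(kernel_matrix(c(1, 2), 1, 0, 1), "degenerate bandwidth")
  expect_silent(kernel_matrix(c(2, 2), 1, 0, 1))
  expect_error(kernel_matrix(c(1, Inf), 1, 1, 1), "times")

  # property: symmetric PSD across random hyperparameters
  set.seed(42)
  for (i in 1:25) {
    times <- sort(runif(sample(2:8, 1), 0, 10))
    K <- kernel_matrix(times, runif(1, 0, 3), runif(1, 0.1, 5), runif(1, 0, 2))
    expect_equal(K, t(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(K)))
  }
})

test_that("GP log likelihood agrees with a dense multivariate-normal oracle", {
  # single flume, single observation, alpha = 0: iid normal density
  d1 <- flume_dataset("f1", "treatment", 2, 3.5)
  expect_equal(gp_log_likelihood(d1, 3, 0.4, 0, 1, 0.5),
               dnorm(3.5, 3.4, 0.5, log = TRUE), tolerance = 1e-10)

  # small instance vs brute-force block MVN
  des <- experiment_design(n_control = 2, n_treatment = 1,
                           sample_times = c(1, 3, 7), beta0 = 3, betaT = 0.5,
                           alpha = 0.4, rho = 2, sigma = 0.3)
  d <- simulate_flume_series(des, seed = 5)
  expect_equal(gp_log_likelihood(d, 3.1, 0.4, 0.5, 1.5, 0.25),
               dense_gp_loglik(d, 3.1, 0.4, 0.5, 1.5, 0.25),
               tolerance = 1e-8)

  # invariance to within-flume observation order
  perm <- unlist(lapply(split(seq_len(nrow(d)), d$flume_id), sample))
  dp <- flume_dataset(d$flume_id[perm], d$group[perm], d$time_h[perm],
                      d$value[perm])
  expect_equal(gp_log_likelihood(dp, 3.1, 0.4, 0.5, 1.5, 0.25),
               gp_log_likelihood(d, 3.1, 0.4, 0.5, 1.5, 0.25),
               tolerance = 1e-10)

  # up to 30 observations, random parameter draws: 1e-8 relative
  set.seed(7)
  for (i in 1:10) {
    des_i <- experiment_design(n_control = sample(1:3, 1),
                               n_treatment = sample(1:2, 1),
                               sample_times = sort(sample(1:12, sample(3:6, 1))),
                               alpha = runif(1, 0.1, 1), rho = runif(1, 0.5, 4),
                               sigma = runif(1, 0.1, 1))
    d_i <- simulate_flume_series(des_i, seed = i)
    b0 <- rnorm(1, 3, 1); bT <- rnorm(1, 0, 0.5)
    a <- runif(1, 0.1, 1); r <- runif(1, 0.5, 4); s <- runif(1, 0.1, 1)
    ours <- gp_log_likelihood(d_i, b0, bT, a, r, s)
    oracle <- dense_gp_loglik(d_i, b0, bT, a, r, s)
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("OLS comparison model equals closed-form normal equations", {
  des <- tiny_design(beta0 = 3, betaT = 0.7, alpha = 0.2, sigma = 0.3)
  d <- simulate_flume_series(des, seed = 9)
  fit <- fit_glm(d)
  # balanced design: betaT is the difference of group means
  expect_equal(fit$betaT,
               mean(d$value[d$group == "treatment"]) -
                 mean(d$value[d$group == "control"]), tolerance = 1e-12)
  # normal equations oracle
  X <- cbind(1, as.integer(d$group == "treatment"))
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$value)
  expect_equal(c(fit$beta0, fit$betaT), as.vector(beta_hat), tolerance = 1e-10)
  resid <- d$value - X %*% beta_hat
  s2 <- sum(resid^2) / (nrow(X) - 2)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(c(fit$se_beta0, fit$se_betaT), unname(se), tolerance = 1e-10)

  # degenerate constant data
  dc <- flume_dataset(rep(c("c1", "t1"), each = 3),
                      rep(c("control", "treatment"), each = 3),
                      rep(1:3, 2), rep(5, 6))
  fc <- fit_glm(dc)
  expect_equal(fc$betaT, 0)
  expect_equal(fc$se_betaT, 0)

  d_one <- flume_dataset("c1", "control", 1, 3)
  expect_error(fit_glm(d_one), "both")
})

test_that("posterior draws, intervals and group means are consistent", {
  des <- default_designs()$doc
  d <- simulate_flume_series(des, seed = 31)
  post <- fit_gp(d, method = "laplace", seed = 2)
  expect_identical(colnames(post$draws),
                   c("beta0", "betaT", "alpha", "rho", "sigma"))
  expect_true(all(post$draws[, 3:5] >= 0))
  expect_lte(post$ci90[1], post$effect_mean)
  expect_gte(post$ci90[2], post$effect_mean)
  gm <- post$group_means
  # draw-wise identity: treatment mean - control mean = effect mean
  expect_equal(gm$mean[gm$group == "treatment"] - gm$mean[gm$group == "control"],
               post$effect_mean, tolerance = 1e-12)
  expect_identical(fit_gp(d, method = "laplace", seed = 2)$draws, post$draws)
  expect_error(predict_group_means(structure(list(draws = post$draws[0, ]),
                                             class = "gp_posterior")),
               "non-empty")
})

test_that("with negligible process variance the GP recovers the OLS estimate", {
  des <- experiment_design(n_control = 5, n_treatment = 5,
                           beta0 = 3, betaT = 0.5, alpha = 0, rho = 2,
                           sigma = 0.3)
  d <- simulate_flume_series(des, seed = 13)
  post <- fit_gp(d, method = "laplace", seed = 3)
  ols <- fit_glm(d)
  # posterior mean of betaT approaches the group-mean difference
  expect_lt(abs(post$effect_mean - ols$betaT), 0.05)
  # and the two models agree within 2 combined SEs
  comb <- sqrt(post$effect_sd^2 + ols$se_betaT^2)
  expect_lt(abs(post$effect_mean - ols$betaT), 2 * comb)
})

test_that("parameters planted in the generator are recovered", {
  des <- default_designs()$doc
  truth <- c(beta0 = des$beta0, betaT = des$betaT, alpha = des$alpha,
             sigma = des$sigma)
  hits <- matrix(FALSE, 20, 4, dimnames = list(NULL, names(truth)))
  rho_ok <- logical(20)
  for (k in 1:20) {
    d <- simulate_flume_series(des, seed = 600 + k)
    post <- fit_gp(d, method = "laplace", seed = 17)
    sm <- summary(post)
    for (p in names(truth)) {
      row <- sm[sm$parameter == p, ]
      hits[k, p] <- abs(row$mean - truth[[p]]) <= 3 * row$sd
    }
    rho_hat <- sm$mean[sm$parameter == "rho"]
    rho_ok[k] <- rho_hat > des$rho / 10 && rho_hat < des$rho * 10
  }
  # each parameter recovered within 3 posterior SDs in >= 90% of replicates
  expect_true(all(colMeans(hits) >= 0.9))
  # rho is weakly identified at 6 time points: order of magnitude only
  expect_true(mean(rho_ok) >= 0.9)
})

test_that("non-convergence is flagged, not silent", {
  des <- default_designs()$doc
  d <- simulate_flume_series(des, seed = 51)
  # starved sampler: too few draws to pass split-Rhat
  expect_warning(post <- fit_gp(d, chains = 4, iter = 40, warmup = 10, seed = 1),
                 "convergence")
  expect_false(post$diagnostics$converged)
})
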