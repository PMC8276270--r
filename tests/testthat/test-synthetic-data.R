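test_that("flume series generator is seed-deterministic and validates input", {
  des <- default_designs()$doc
  a <- simulate_flume_series(des, seed = 11)
  b <- simulate_flume_series(des, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_flume_series(des, seed = 12)))
  # RNG state of the caller is untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_flume_series(des, seed = 5))
  expect_identical(before, .Random.seed)

  expect_error(experiment_design(n_control = 0), "n_control")
  expect_error(experiment_design(sample_times = c(2, 1)), "sample_times")
  expect_error(experiment_design(alpha = -1), "alpha")
  expect_error(experiment_design(sigma = NA), "sigma")
})

test_that("null treatment effect leaves group means centred on zero", {
  des <- experiment_design(n_control = 2, n_treatment = 2, betaT = 0,
                           beta0 = 3, alpha = 0.3, rho = 2, sigma = 0.2)
  diffs <- vapply(1:1000, function(s) {
    d <- simulate_flume_series(des, seed = s)
    mean(d$value[d$group == "treatment"]) - mean(d$value[d$group == "control"])
  }, numeric(1))
  # each diff has variance 2/2 * (alpha^2 cbar + sigma^2/6) ~ 0.08;
  # MC standard error of the mean over 1000 replicates
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se)
})

test_that("empirical within-flume covariance matches the kernel", {
  des <- experiment_design(n_control = 1, n_treatment = 1, betaT = 0,
                           beta0 = 0, alpha = 1, rho = 2, sigma = 0.1)
  n_rep <- 4000
  Y <- t(vapply(1:n_rep, function(s) {
    d <- simulate_flume_series(des, seed = s)
    d$value[d$group == "control"]
  }, numeric(6)))
  K_emp <- cov(Y)
  K <- kernel_matrix(des$sample_times, 1, 2, 0.1)
  # sampling error of a covariance entry is O(K_ii K_jj / sqrt(n))
  expect_lt(max(abs(K_emp - K)), 6 / sqrt(n_rep))
})

test_that("marginal variance at any time equals alpha^2 + sigma^2", {
  des <- experiment_design(n_control = 1, n_treatment = 1, betaT = 0,
                           beta0 = 0, alpha = 0.5, rho = 2, sigma = 0.3)
  n_rep <- 10000
  Y <- t(vapply(1:n_rep, function(s) {
    simulate_flume_series(des, seed = s)$value[1:6]
  }, numeric(6)))
  v_emp <- apply(Y, 2, var)
  v_true <- 0.5^2 + 0.3^2
  # variance of a sample variance: 2 v^2 / (n - 1); 3 MC SEs
  mc_se <- sqrt(2 * v_true^2 / (n_rep - 1))
  expect_true(all(abs(v_emp - v_true) < 3 * mc_se + 0.01 * v_true))
})

test_that("synthetic EEMs are trilinear, nonnegative and peak-faithful", {
  des1 <- coarse_eem_design(n_samples = 3)
  des1$components <- des1$components[1, , drop = FALSE]
  des1 <- eem_design(ex_grid = des1$ex_grid, em_grid = des1$em_grid,
                     components = des1$components, n_samples = 3,
                     noise_sd = 0, scatter = FALSE)
  cube <- simulate_eems(des1, seed = 2)
  # noiseless single component: every EEM is rank 1
  for (i in 1:3) {
    sv <- svd(cube$intensities[i, , ])$d
    expect_lt(sv[2] / sv[1], 1e-10)
  }
  expect_true(all(cube$intensities >= 0))

  # four study components: each pure profile peaks at its specification
  des4 <- eem_design(n_samples = 4, noise_sd = 0)
  cube4 <- simulate_eems(des4, seed = 3)
  truth <- attr(cube4, "truth")
  for (r in 1:4) {
    expect_equal(des4$ex_grid[which.max(truth$ex_loadings[, r])],
                 des4$components$ex_peak[r])
    expect_equal(des4$em_grid[which.max(truth$em_loadings[, r])],
                 des4$components$em_peak[r])
  }
  expect_equal(des4$components$ex_peak, c(250, 360, 285, 265))
  expect_equal(des4$components$em_peak, c(425, 465, 500, 335))

  # exact reconstruction from the attached factors when noiseless
  A <- truth$sample_loadings; B <- truth$ex_loadings; C <- truth$em_loadings
  for (i in 1:4) {
    M <- B %*% diag(A[i, ]) %*% t(C)
    expect_lt(max(abs(M - cube4$intensities[i, , ])), 1e-10)
  }

  # validation
  expect_error(eem_design(components = data.frame(
    ex_peak = 300, ex_width = 20, em_peak = 280, em_width = 20)), "Stokes")
  expect_error(simulate_eems(des4, sample_loadings = matrix(-1, 4, 4)),
               "nonnegative")
  expect_identical(simulate_eems(des4, seed = 9), simulate_eems(des4, seed = 9))
})

test_that("enzyme plate generator honours multipliers and seeds", {
  mult1 <- c(glu = 1, xyl = 1, cbh = 1, nag = 1, pho = 1, lip = 1,
             pep = 1, pox = 1)
  t0 <- simulate_enzyme_plate(group_multipliers = mult1, cv = 0, seed = 4)
  expect_equal(unname(as.matrix(t0[t0$group == "control", ENZ <- c("glu","xyl","cbh","nag","pho","lip","pep","pox")])),
               unname(as.matrix(t0[t0$group == "treatment", ENZ])))

  mult <- mult1; mult["pox"] <- 2; mult["glu"] <- 0.5
  t1 <- simulate_enzyme_plate(group_multipliers = mult, cv = 0, seed = 4)
  r <- enzyme_ratios(t1)
  ctrl <- r$glu_pox[r$group == "control"]
  trt <- r$glu_pox[r$group == "treatment"]
  expect_equal(trt, ctrl / 4)

  expect_identical(simulate_enzyme_plate(seed = 8), simulate_enzyme_plate(seed = 8))
  expect_error(simulate_enzyme_plate(base_activities = c(glu = -1)), "base_activities")
  expect_error(simulate_enzyme_plate(cv = -0.1), "cv")
})

test_that("flume dataset CSV round-trips", {
  des <- tiny_design()
  d <- simulate_flume_series(des, seed = 21)
  p <- tempfile(fileext = ".csv")
  write_flume_csv(d, p)
  d2 <- read_flume_csv(p, response = "doc")
  expect_equal(as.data.frame(d), as.data.frame(d2), tolerance = 1e-12)
})
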