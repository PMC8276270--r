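test_that("noiseless rank-1 cube is fit essentially exactly", {
  des <- coarse_eem_design(n_samples = 5, components =
    data.frame(ex_peak = 320, ex_width = 40, em_peak = 460, em_width = 50))
  cube <- simulate_eems(des, seed = 21)
  m <- fit_parafac(cube, 1, n_starts = 2, seed = 6)
  expect_gt(m$explained_variance, 0.9999)
  truth <- attr(cube, "truth")
  # recovered spectral profiles proportional to the generating ones
  cor_ex <- cor(m$ex_loadings[, 1], truth$ex_loadings[, 1])
  cor_em <- cor(m$em_loadings[, 1], truth$em_loadings[, 1])
  expect_gt(cor_ex, 0.99999)
  expect_gt(cor_em, 0.99999)
  # relative reconstruction error < 1e-6 on a noiseless trilinear fixture
  expect_lt(sqrt(m$sse / sum(cube$intensities^2)), 1e-6)
})

test_that("four planted components are recovered within one grid step", {
  des <- coarse_eem_design(n_samples = 12, noise_sd = 0.02)
  cube <- contrast_cube(12, seed = 22)
  m <- fit_parafac(cube, 4, n_starts = 4, seed = 7)
  idx <- match_components(m, des$components)
  mx <- component_maxima(m)
  step <- 10  # coarse fixture grid
  for (r in 1:4) {
    expect_lte(abs(mx$ex_peak[idx[r]] - des$components$ex_peak[r]), step)
    expect_lte(abs(mx$em_peak[idx[r]] - des$components$em_peak[r]), step)
  }
  # components are ordered by energy, descending
  expect_true(all(diff(colSums(m$sample_loadings^2)) <= 1e-8))
  # loadings are nonnegative everywhere
  expect_true(all(m$sample_loadings >= 0) && all(m$ex_loadings >= 0) &&
                all(m$em_loadings >= 0))
})

test_that("ALS objective is monotone non-increasing", {
  des <- coarse_eem_design(n_samples = 6, noise_sd = 0.05)
  cube <- simulate_eems(des, seed = 23)
  m <- fit_parafac(cube, 3, n_starts = 1, seed = 8)
  tr <- m$sse_trace
  expect_true(all(diff(tr) <= 1e-9 * tr[-length(tr)] + 1e-12))
  # with masked cells the objective stays monotone too (EM imputation)
  mm <- fit_parafac(remove_rayleigh(cube, 10), 3, n_starts = 1, seed = 8)
  tr2 <- mm$sse_trace
  expect_true(all(diff(tr2) <= 1e-9 * tr2[-length(tr2)] + 1e-12))
})

test_that("recovery is invariant to the random start seed", {
  cube <- contrast_cube(10, seed = 24)
  m1 <- fit_parafac(cube, 4, n_starts = 4, seed = 1)
  m2 <- fit_parafac(cube, 4, n_starts = 4, seed = 999)
  idx <- match_components(m2, component_maxima(m1)[, c("ex_peak", "em_peak")])
  expect_equal(component_maxima(m1)$ex_peak,
               component_maxima(m2)$ex_peak[idx])
  expect_equal(component_maxima(m1)$em_peak,
               component_maxima(m2)$em_peak[idx])
  # byte-determinism for equal seeds
  expect_identical(fit_parafac(cube, 2, n_starts = 2, seed = 5),
                   fit_parafac(cube, 2, n_starts = 2, seed = 5))
})

test_that("leverage scores follow projector algebra", {
  # full-rank square loading matrix: every leverage is 1
  set.seed(3)
  A_sq <- matrix(runif(9, 0.2, 1), 3, 3)
  m_sq <- fake_parafac_model(A_sq, A_sq, A_sq)
  expect_equal(leverage_scores(m_sq, "sample"), rep(1, 3), tolerance = 1e-8)

  # identical single-component loadings: leverage = n_components / n_samples
  A1 <- matrix(0.7, 10, 1)
  m1 <- fake_parafac_model(A1, A1, A1)
  expect_equal(leverage_scores(m1, "sample"), rep(1 / 10, 10), tolerance = 1e-10)

  # identical multi-component loadings are rank deficient -> informative error
  A2 <- matrix(rep(c(0.3, 0.7), each = 6), 6, 2)
  A2[, 2] <- A2[, 1]
  m2 <- fake_parafac_model(A2, A2, A2)
  expect_error(leverage_scores(m2, "sample"), "rank deficient")

  # leverage sums to the component count on real fits, all modes
  cube <- contrast_cube(9, seed = 25, noise_sd = 0.03)
  m <- fit_parafac(cube, 4, n_starts = 3, seed = 9)
  for (mode in c("sample", "ex", "em")) {
    lev <- leverage_scores(m, mode)
    expect_true(all(lev >= -1e-10 & lev <= 1 + 1e-10))
    expect_equal(sum(lev), 4, tolerance = 1e-8)
  }
})

test_that("a planted outlier sample attains the maximum leverage", {
  des <- coarse_eem_design(n_samples = 8, noise_sd = 0.01, components =
    data.frame(ex_peak = c(300, 400), ex_width = c(30, 30),
               em_peak = c(430, 520), em_width = c(40, 40)))
  A <- cbind(runif_seeded <- rep(1, 8), rep(0, 8))
  A[8, ] <- c(0, 1.5)   # one sample made of a unique extra component
  cube <- simulate_eems(des, sample_loadings = A, seed = 26)
  m <- fit_parafac(cube, 2, n_starts = 3, seed = 10)
  lev <- leverage_scores(m, "sample")
  expect_equal(which.max(lev), 8L)
  expect_true(8L %in% flag_outliers(m))
})

test_that("component maxima use the grid and the documented tie-break", {
  B <- matrix(0, 5, 1); B[3, 1] <- 1
  C <- matrix(0, 4, 1); C[2, 1] <- 2
  m <- fake_parafac_model(matrix(1, 2, 1), B, C,
                          ex = c(250, 260, 270, 280, 290),
                          em = c(300, 320, 340, 360))
  mx <- component_maxima(m)
  expect_equal(mx$ex_peak, 270)
  expect_equal(mx$em_peak, 320)

  # flat loading vector: tie broken toward the shortest wavelength
  Bf <- matrix(1, 5, 1)
  mf <- fake_parafac_model(matrix(1, 2, 1), Bf, C,
                           ex = c(250, 260, 270, 280, 290),
                           em = c(300, 320, 340, 360))
  expect_equal(component_maxima(mf)$ex_peak, 250)

  # all-zero loading vector: undefined peak
  Bz <- matrix(0, 5, 1)
  mz <- fake_parafac_model(matrix(1, 2, 1), Bz, C,
                           ex = c(250, 260, 270, 280, 290),
                           em = c(300, 320, 340, 360))
  expect_error(component_maxima(mz), "undefined")
})

test_that("fewer components than the truth explain materially less variance", {
  cube <- contrast_cube(10, seed = 27)
  m1 <- fit_parafac(cube, 1, n_starts = 2, seed = 11)
  m4 <- fit_parafac(cube, 4, n_starts = 3, seed = 11)
  expect_gt(m4$explained_variance, m1$explained_variance + 0.1)
})

test_that("parafac export writes the three per-mode CSVs", {
  des <- coarse_eem_design(n_samples = 5, noise_sd = 0.02)
  cube <- simulate_eems(des, seed = 28)
  m <- fit_parafac(cube, 2, n_starts = 1, seed = 12)
  dir <- tempfile()
  export_parafac(m, dir)
  ex <- read.csv(file.path(dir, "ex_loadings.csv"))
  expect_identical(names(ex), c("wavelength_nm", "C1", "C2"))
  expect_equal(ex$wavelength_nm, m$ex_grid)
  expect_equal(as.matrix(ex[, 2:3]), m$ex_loadings, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "sample_loadings.csv")))
  expect_true(file.exists(file.path(dir, "em_loadings.csv")))
})
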