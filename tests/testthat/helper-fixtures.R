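# Shared fixtures, built in code at test time.

# small flume design for cheap fits
tiny_design <- function(...) {
  experiment_design(n_control = 2, n_treatment = 2,
                    sample_times = c(1, 2, 4), ...)
}

# coarse EEM design (10 nm grids) keeping the four study peak positions
# representable; cheap enough for repeated PARAFAC fits
coarse_eem_design <- function(n_samples = 10, noise_sd = 0, scatter = FALSE,
                              components = NULL) {
  if (is.null(components))
    components <- data.frame(ex_peak = c(250, 360, 290, 270),
                             ex_width = c(30, 35, 30, 25),
                             em_peak = c(430, 470, 500, 340),
                             em_width = c(45, 45, 50, 35))
  eem_design(ex_grid = seq(250, 550, by = 10),
             em_grid = seq(250, 600, by = 10),
             components = components, n_samples = n_samples,
             noise_sd = noise_sd, scatter = scatter)
}

# coarse cube with high-contrast explicit sample loadings; the wider
# loading spread (0.1-2) keeps the trilinear problem well conditioned at
# small sample counts, where near-constant loadings make ALS collapse
contrast_cube <- function(n_samples, seed, noise_sd = 0.02, design = NULL) {
  des <- design %||% coarse_eem_design(n_samples = n_samples,
                                       noise_sd = noise_sd)
  des$n_samples <- n_samples
  R <- nrow(des$components)
  A <- local({ set.seed(seed + 1); matrix(runif(n_samples * R, 0.1, 2),
                                          n_samples, R) })
  simulate_eems(des, sample_loadings = A, seed = seed)
}

# independent dense multivariate-normal log density (solve/determinant,
# no Cholesky sharing with the implementation under test)
dense_mvn_logpdf <- function(y, mu, K) {
  r <- y - mu
  q <- drop(t(r) %*% solve(K) %*% r)
  -0.5 * q - 0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
    0.5 * length(y) * log(2 * pi)
}

# stack a flume dataset into one dense block-diagonal MVN and evaluate
dense_gp_loglik <- function(dataset, beta0, betaT, alpha, rho, sigma) {
  ll <- 0
  for (id in unique(dataset$flume_id)) {
    rows <- dataset$flume_id == id
    t_f <- dataset$time_h[rows]
    K <- alpha^2 * exp(-outer(t_f, t_f, "-")^2 / (2 * rho^2)) +
      sigma^2 * diag(length(t_f))
    mu <- rep(beta0 + betaT * (dataset$group[rows][1] == "treatment"),
              length(t_f))
    ll <- ll + dense_mvn_logpdf(dataset$value[rows], mu, K)
  }
  ll
}

# minimal hand-built parafac_model for projector algebra tests
fake_parafac_model <- function(A, B, C, ex = NULL, em = NULL) {
  structure(list(n_components = ncol(A), sample_loadings = A,
                 ex_loadings = B, em_loadings = C,
                 ex_grid = ex %||% seq_len(nrow(B)),
                 em_grid = em %||% seq_len(nrow(C))),
            class = "parafac_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
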