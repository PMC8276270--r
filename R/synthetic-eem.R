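#' Design for the synthetic EEM generator
#'
#' Describes the instrument grid and the fluorophore components used to
#' build trilinear synthetic EEMs.  The default grid matches the
#' spectrofluorometer setup of the motivating study (excitation 250-550
#' nm, emission 250-600 nm, 5 nm increments) and the four default
#' components sit at the excitation/emission maxima of the study's
#' PARAFAC components: (250, 425), (360, 465), (285, 500) and
#' (265, 335) nm.  Component line shapes are Gaussian in both modes —
#' the simplest shape with clean, recoverable maxima.
#'
#' @param ex_grid,em_grid strictly increasing wavelength grids (nm).
#' @param components data.frame with columns `ex_peak`, `ex_width`,
#'   `em_peak`, `em_width` (nm); peaks must lie inside the grids, widths
#'   be positive, and each component must have `em_peak > ex_peak`
#'   (Stokes shift).
#' @param n_samples number of EEMs to simulate.
#' @param noise_sd i.i.d. Gaussian noise SD in intensity units (component
#'   profiles peak at 1, so 0.05 is "5 % of a unit peak").
#' @param scatter logical; inject first- (`em = ex`) and second-order
#'   (`em = 2 ex`) scatter ridges (triangular cross-section, 10 nm
#'   half-width).
#' @return An `eem_design` list.
#' @export
eem_design <- function(ex_grid = seq(250, 550, by = 5),
                       em_grid = seq(250, 600, by = 5),
                       components = data.frame(
                         ex_peak = c(250, 360, 285, 265),
                         ex_width = c(30, 35, 30, 25),
                         em_peak = c(425, 465, 500, 335),
                         em_width = c(45, 45, 50, 35)),
                       n_samples = 30, noise_sd = 0.05, scatter = FALSE) {
  assert_increasing(ex_grid, "ex_grid")
  assert_increasing(em_grid, "em_grid")
  need <- c("ex_peak", "ex_width", "em_peak", "em_width")
  if (!is.data.frame(components) || !all(need %in% names(components)) ||
      nrow(components) < 1L)
    abort_field("components", "must be a data.frame with ex_peak, ex_width, em_peak, em_width")
  if (any(components$ex_peak < min(ex_grid) | components$ex_peak > max(ex_grid)))
    abort_field("components$ex_peak", "peaks must lie inside ex_grid")
  if (any(components$em_peak < min(em_grid) | components$em_peak > max(em_grid)))
    abort_field("components$em_peak", "peaks must lie inside em_grid")
  if (any(components$em_peak <= components$ex_peak))
    abort_field("components", "em_peak must exceed ex_peak (Stokes shift)")
  if (any(components$ex_width <= 0) || any(components$em_width <= 0))
    abort_field("components", "widths must be > 0")
  n_samples <- assert_count(n_samples, "n_samples")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(list(ex_grid = as.numeric(ex_grid), em_grid = as.numeric(em_grid),
                 components = components, n_samples = n_samples,
                 noise_sd = noise_sd, scatter = isTRUE(scatter)),
            class = "eem_design")
}

gauss_profile <- function(grid, peak, width) {
  exp(-(grid - peak)^2 / (2 * width^2))
}

#' Simulate a cube of trilinear synthetic EEMs
#'
#' Each sample EEM is a nonnegative mixture
#' `sum_r a[i, r] * b_r(ex) %o% c_r(em)` of Gaussian-peaked excitation and
#' emission profiles (each profile normalized to peak height 1), plus
#' i.i.d. Gaussian noise and, optionally, first/second-order scatter
#' ridges.  The true factor matrices are attached as attribute `"truth"`
#' for recovery studies.
#'
#' @param design an [eem_design()].
#' @param sample_loadings `"random"` (default: i.i.d. Uniform(0.5, 1.5))
#'   or a nonnegative `n_samples x n_components` matrix.
#' @param seed integer seed.
#' @return An [eem_cube()] with attribute `truth` = list(`sample_loadings`,
#'   `ex_loadings`, `em_loadings`, `design`).
#' @export
simulate_eems <- function(design, sample_loadings = "random", seed = 1L) {
  if (!inherits(design, "eem_design"))
    abort_field("design", "must be an eem_design")
  R <- nrow(design$components)
  n <- design$n_samples
  B <- vapply(seq_len(R), function(r)
    gauss_profile(design$ex_grid, design$components$ex_peak[r],
                  design$components$ex_width[r]), numeric(length(design$ex_grid)))
  C <- vapply(seq_len(R), function(r)
    gauss_profile(design$em_grid, design$components$em_peak[r],
                  design$components$em_width[r]), numeric(length(design$em_grid)))
  with_seed(seed, {
    if (identical(sample_loadings, "random")) {
      A <- matrix(stats::runif(n * R, 0.5, 1.5), n, R)
    } else {
      A <- as.matrix(sample_loadings)
      if (!is.numeric(A) || any(A < 0) || nrow(A) != n || ncol(A) != R)
        abort_field("sample_loadings",
                    "must be a nonnegative n_samples x n_components matrix")
    }
    J <- length(design$ex_grid); K <- length(design$em_grid)
    X <- array(0, c(n, J, K))
    base <- array(0, c(J, K))
    if (design$scatter) {
      hw <- 10  # nm half-width of the injected scatter ridge
      d1 <- abs(outer(design$ex_grid, design$em_grid, function(e, m) m - e))
      d2 <- abs(outer(design$ex_grid, design$em_grid, function(e, m) m - 2 * e))
      base <- pmax(1 - d1 / hw, 0) + 0.5 * pmax(1 - d2 / hw, 0)
    }
    for (i in seq_len(n)) {
      M <- B %*% (A[i, ] * t(C)) + base
      if (design$noise_sd > 0)
        M <- M + matrix(stats::rnorm(J * K, 0, design$noise_sd), J, K)
      X[i, , ] <- M
    }
    out <- eem_cube(design$ex_grid, design$em_grid, X)
    attr(out, "truth") <- list(sample_loadings = A, ex_loadings = B,
                               em_loadings = C, design = design)
    out
  })
}
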