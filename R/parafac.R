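#' Nonnegative PARAFAC decomposition of an EEM cube
#'
#' Trilinear decomposition
#' `X[i, j, k] ~ sum_r A[i, r] * B[j, r] * C[k, r]` of a
#' `samples x excitation x emission` fluorescence array with
#' nonnegativity constraints on all three modes, fitted by hierarchical
#' alternating least squares (column-wise HALS updates, each block update
#' non-increasing in the least-squares objective).  Masked (missing)
#' cells — e.g. deleted scatter bands — are excluded from the objective
#' via expectation-maximization imputation: at every iteration they are
#' replaced by the current model value, so they never pull the fit.
#'
#' The best of `n_starts` random initializations is kept; the run is
#' reproducible for a fixed `seed`.  After fitting, excitation and
#' emission loadings are scaled to unit Euclidean norm (magnitude lives
#' in the sample mode) and components are ordered by explained variance,
#' descending.
#'
#' @param cube an [eem_cube()] with at least `n_components` samples.
#' @param n_components number of components (>= 1, <= every cube dimension).
#' @param n_starts random initializations (default 10).
#' @param tol convergence tolerance on the relative change of the
#'   observed-cell SSE (default 1e-8).
#' @param max_iter iteration cap per start (default 2500).
#' @param seed integer seed.
#' @return A `parafac_model`: loading matrices `sample_loadings`,
#'   `ex_loadings`, `em_loadings`; `sse` (observed cells);
#'   `explained_variance`; `sse_trace` of the winning start; and a
#'   `convergence` list (`iterations`, `rel_change`, `converged`).
#' @export
fit_parafac <- function(cube, n_components, n_starts = 10, tol = 1e-8,
                        max_iter = 2500, seed = 1L) {
  if (!inherits(cube, "eem_cube"))
    abort_field("cube", "must be an eem_cube")
  d <- dim(cube$intensities)
  n_components <- assert_count(n_components, "n_components")
  if (n_components > min(d))
    abort_field("n_components", "exceeds the smallest cube dimension")
  n_starts <- assert_count(n_starts, "n_starts")
  max_iter <- assert_count(max_iter, "max_iter")
  assert_scalar_number(tol, "tol", lower = 0)

  X <- cube$intensities
  miss <- cube$mask
  obs <- !miss
  # negative observed values (blank subtraction noise) cannot be matched
  # by a nonnegative model; clip to zero as is standard practice
  X[obs & X < 0] <- 0
  X[miss] <- mean(X[obs])
  ss_tot <- sum(X[obs]^2)

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      res <- parafac_als(X, miss, obs, n_components, tol, max_iter)
      if (is.null(best) || res$sse < best$sse) best <- res
    }
  })

  A <- best$A; B <- best$B; C <- best$C
  # unit-norm spectral loadings, magnitude into the sample mode
  nb <- sqrt(colSums(B^2)); nc <- sqrt(colSums(C^2))
  nb[nb == 0] <- 1; nc[nc == 0] <- 1
  B <- sweep(B, 2, nb, "/"); C <- sweep(C, 2, nc, "/")
  A <- sweep(A, 2, nb * nc, "*")
  # order by per-component energy (with unit-norm B, C this is ||A_r||^2)
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]

  structure(list(n_components = n_components,
                 sample_loadings = A, ex_loadings = B, em_loadings = C,
                 ex_grid = cube$ex, em_grid = cube$em,
                 sample_ids = cube$sample_ids,
                 sse = best$sse,
                 explained_variance = 1 - best$sse / ss_tot,
                 sse_trace = best$trace,
                 convergence = list(iterations = best$iterations,
                                    rel_change = best$rel_change,
                                    converged = best$converged),
                 n_starts = n_starts, tol = tol, seed = seed),
            class = "parafac_model")
}

# Khatri-Rao product (column-wise Kronecker), first argument varying slowest.
khatri_rao <- function(U, V) {
  R <- ncol(U)
  out <- matrix(0, nrow(U) * nrow(V), R)
  for (r in seq_len(R)) out[, r] <- as.vector(V[, r] %o% U[, r])
  out
}

# One nonnegative ALS run from a random start.  X has missing cells
# pre-filled; `miss`/`obs` index them.  Returns loadings and the observed
# SSE trace.
parafac_als <- function(X, miss, obs, R, tol, max_iter) {
  d <- dim(X)
  n <- d[1]; J <- d[2]; K <- d[3]
  any_miss <- any(miss)
  A <- matrix(stats::runif(n * R, 0.1, 1), n, R)
  B <- matrix(stats::runif(J * R, 0.1, 1), J, R)
  C <- matrix(stats::runif(K * R, 0.1, 1), K, R)

  hals_update <- function(M, P, G) {
    # minimize ||X - M t(KR)||^2 column-block-wise under M >= 0
    for (r in seq_len(R)) {
      g <- G[r, r]
      if (g < 1e-12) { M[, r] <- 1e-9; next }
      M[, r] <- pmax(0, M[, r] + (P[, r] - M %*% G[, r]) / g)
    }
    M
  }

  sse_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  rel <- NA_real_
  it <- 0L
  X1 <- matrix(X, n, J * K)                     # j fastest, then k
  for (it in seq_len(max_iter)) {
    KR1 <- khatri_rao(C, B)                     # (j fastest) x R
    A <- hals_update(A, X1 %*% KR1, crossprod(B) * crossprod(C))
    X2 <- matrix(aperm(X, c(2, 1, 3)), J, n * K)  # i fastest, then k
    KR2 <- khatri_rao(C, A)
    B <- hals_update(B, X2 %*% KR2, crossprod(A) * crossprod(C))
    X3 <- matrix(aperm(X, c(3, 1, 2)), K, n * J)  # i fastest, then j
    KR3 <- khatri_rao(B, A)
    C <- hals_update(C, X3 %*% KR3, crossprod(A) * crossprod(B))

    M1 <- A %*% t(khatri_rao(C, B))             # model, mode-1 unfolding
    Xhat <- array(M1, c(n, J, K))
    sse <- sum((X[obs] - Xhat[obs])^2)
    trace <- c(trace, sse)
    if (any_miss) {
      X[miss] <- Xhat[miss]                     # EM step for masked cells
      X1 <- matrix(X, n, J * K)
    }
    rel <- if (is.finite(sse_prev)) abs(sse_prev - sse) / max(sse_prev, 1e-300) else Inf
    if (is.finite(sse_prev) && rel < tol) { converged <- TRUE; break }
    sse_prev <- sse
  }
  list(A = A, B = B, C = C, sse = trace[length(trace)], trace = trace,
       iterations = it, rel_change = rel, converged = converged)
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("<parafac_model> %d components, %d samples, explained variance %.4f\n",
              x$n_components, nrow(x$sample_loadings), x$explained_variance))
  mx <- component_maxima(x)
  for (r in seq_len(nrow(mx)))
    cat(sprintf("  C%d: ex max %g nm, em max %g nm\n", r,
                mx$ex_peak[r], mx$em_peak[r]))
  cat(sprintf("  converged: %s after %d iterations (rel change %.2e)\n",
              x$convergence$converged, x$convergence$iterations,
              x$convergence$rel_change))
  invisible(x)
}

#' Leverage of each item of one PARAFAC mode
#'
#' Diagonal of the hat projector `A (A'A)^-1 A'` of the requested mode's
#' loading matrix: values in `[0, 1]` summing to the number of
#' components.  High-leverage samples dominate the fit and are outlier
#' candidates.
#'
#' @param model a fitted `parafac_model`.
#' @param mode `"sample"`, `"ex"` or `"em"`.
#' @return Numeric vector of leverages.
#' @export
leverage_scores <- function(model, mode = c("sample", "ex", "em")) {
  stopifnot(inherits(model, "parafac_model"))
  mode <- match.arg(mode)
  A <- switch(mode, sample = model$sample_loadings,
              ex = model$ex_loadings, em = model$em_loadings)
  G <- crossprod(A)
  Gi <- tryCatch(solve(G), error = function(e)
    stop("loading matrix is rank deficient; reduce the number of components",
         call. = FALSE))
  rowSums((A %*% Gi) * A)
}

#' Flag high-leverage samples
#'
#' Samples whose leverage exceeds `threshold` or `relative` times the
#' mean leverage (`n_components / n_samples`) are flagged for exclusion
#' and refitting.
#'
#' @param model a `parafac_model`.
#' @param threshold absolute leverage cutoff (default 0.15).
#' @param relative multiple-of-mean cutoff (default 2).
#' @return Integer indices of flagged samples (possibly empty).
#' @export
flag_outliers <- function(model, threshold = 0.15, relative = 2) {
  lev <- leverage_scores(model, "sample")
  which(lev > threshold | lev > relative * mean(lev))
}

#' Excitation and emission maxima of each component
#'
#' Argmax of each loading vector reported on the wavelength grid; ties
#' are broken toward the shorter wavelength.
#'
#' @param model a `parafac_model`.
#' @return data.frame with columns `component`, `ex_peak`, `em_peak` (nm).
#' @export
component_maxima <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  peak <- function(load, grid, what) {
    if (all(load == 0))
      stop("undefined peak: all-zero ", what, " loading vector", call. = FALSE)
    grid[which.max(load)]   # which.max returns the first (shortest) maximum
  }
  data.frame(
    component = seq_len(model$n_components),
    ex_peak = vapply(seq_len(model$n_components), function(r)
      peak(model$ex_loadings[, r], model$ex_grid, "excitation"), numeric(1)),
    em_peak = vapply(seq_len(model$n_components), function(r)
      peak(model$em_loadings[, r], model$em_grid, "emission"), numeric(1)))
}

#' Match fitted components to reference peak positions
#'
#' Finds the assignment of fitted components to reference components that
#' minimizes the summed absolute excitation + emission peak distance
#' (exhaustive over permutations; intended for <= ~6 components).
#'
#' @param model a `parafac_model`.
#' @param ref_peaks data.frame with columns `ex_peak`, `em_peak` (nm).
#' @return Integer vector `m` such that fitted component `m[r]` matches
#'   reference component `r`.
#' @export
match_components <- function(model, ref_peaks) {
  mx <- component_maxima(model)
  R <- nrow(ref_peaks)
  stopifnot(model$n_components == R)
  cost <- outer(seq_len(R), seq_len(R), Vectorize(function(fit, ref)
    abs(mx$ex_peak[fit] - ref_peaks$ex_peak[ref]) +
      abs(mx$em_peak[fit] - ref_peaks$em_peak[ref])))
  perms <- all_permutations(R)
  costs <- vapply(perms, function(p) sum(cost[cbind(p, seq_len(R))]), numeric(1))
  perms[[which.min(costs)]]
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      q <- integer(n); q[1] <- i
      rest <- setdiff(seq_len(n), i)
      q[-1] <- rest[p]
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

#' Split-half stability diagnostic for the component number
#'
#' Splits the samples into two halves (odd/even), fits each half with the
#' same settings, and reports the Tucker congruence coefficient of the
#' matched excitation and emission loadings.  Values near 1 support the
#' chosen number of components; this is an optional diagnostic, not a
#' formal test.
#'
#' @param cube an [eem_cube()].
#' @param n_components components to fit in each half.
#' @param ... passed to [fit_parafac()].
#' @return data.frame with per-component congruence for both modes.
#' @export
split_half_congruence <- function(cube, n_components, ...) {
  n <- dim(cube$intensities)[1]
  h1 <- seq(1, n, by = 2); h2 <- seq(2, n, by = 2)
  sub <- function(idx) eem_cube(cube$ex, cube$em,
                                cube$intensities[idx, , , drop = FALSE],
                                cube$mask[idx, , , drop = FALSE])
  f1 <- fit_parafac(sub(h1), n_components, ...)
  f2 <- fit_parafac(sub(h2), n_components, ...)
  m <- match_components(f2, component_maxima(f1)[, c("ex_peak", "em_peak")])
  tucker <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  data.frame(
    component = seq_len(n_components),
    ex_congruence = vapply(seq_len(n_components), function(r)
      tucker(f1$ex_loadings[, r], f2$ex_loadings[, m[r]]), numeric(1)),
    em_congruence = vapply(seq_len(n_components), function(r)
      tucker(f1$em_loadings[, r], f2$em_loadings[, m[r]]), numeric(1)))
}

#' Export PARAFAC loadings as per-mode CSV files
#'
#' Writes `sample_loadings.csv`, `ex_loadings.csv` and `em_loadings.csv`
#' (index/wavelength column plus one column per component, an
#' OpenFluor-style layout) into `dir`.
#'
#' @param model a `parafac_model`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_parafac <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cn <- paste0("C", seq_len(model$n_components))
  write1 <- function(first, mat, fname, first_name) {
    df <- data.frame(first, mat)
    names(df) <- c(first_name, cn)
    p <- file.path(dir, fname)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(
    write1(model$sample_ids, model$sample_loadings, "sample_loadings.csv", "sample"),
    write1(model$ex_grid, model$ex_loadings, "ex_loadings.csv", "wavelength_nm"),
    write1(model$em_grid, model$em_loadings, "em_loadings.csv", "wavelength_nm"))
  invisible(paths)
}
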