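#' Absorbance spectrum container and SUVA254
#'
#' `absorbance_spectrum()` stores a decadal absorbance spectrum measured
#' in a cuvette of known path length; `suva254()` converts it to the
#' specific UV absorbance at 254 nm, the standard aromaticity proxy for
#' dissolved organic matter:
#' `SUVA254 = a(254) / DOC` with `a(254)` the decadal absorption
#' coefficient in 1/m (absorbance divided by path length in metres) and
#' DOC in mg C/L, giving L mg-C^-1 m^-1.
#'
#' @param wavelengths strictly increasing wavelengths (nm).
#' @param absorbance decadal absorbance (unitless), same length.
#' @param path_length_cm cuvette path length in cm (> 0), default 1 cm.
#' @return `absorbance_spectrum()`: an `absorbance_spectrum` object.
#' @export
absorbance_spectrum <- function(wavelengths, absorbance, path_length_cm = 1) {
  assert_increasing(wavelengths, "wavelengths")
  if (!is.numeric(absorbance) || length(absorbance) != length(wavelengths) ||
      any(!is.finite(absorbance)))
    abort_field("absorbance", "must be finite and match wavelengths in length")
  assert_scalar_number(path_length_cm, "path_length_cm", lower = 0, strict = TRUE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = as.numeric(absorbance),
                 path_length_cm = path_length_cm),
            class = "absorbance_spectrum")
}

#' @param spectrum an [absorbance_spectrum()] whose range covers 254 nm.
#' @param doc dissolved organic carbon concentration (mg C/L, > 0).
#' @return `suva254()`: SUVA254 in L mg-C^-1 m^-1.  Absorbance is
#'   linearly interpolated between the neighbouring grid points (254 nm
#'   falls between the 250 and 255 nm points of a 5 nm grid).
#' @rdname absorbance_spectrum
#' @export
suva254 <- function(spectrum, doc) {
  if (!inherits(spectrum, "absorbance_spectrum"))
    abort_field("spectrum", "must be an absorbance_spectrum")
  assert_scalar_number(doc, "doc", lower = 0, strict = TRUE)
  wl <- spectrum$wavelengths
  if (254 < min(wl) || 254 > max(wl))
    stop("254 nm is outside the measured wavelength range [",
         min(wl), ", ", max(wl), "] nm", call. = FALSE)
  a254 <- stats::approx(wl, spectrum$absorbance, xout = 254)$y
  path_m <- spectrum$path_length_cm / 100
  (a254 / path_m) / doc
}

#' Excitation-emission matrix (EEM) containers
#'
#' `eem()` holds one fluorescence landscape: intensity over an excitation
#' x emission wavelength grid plus a logical mask marking missing
#' (deleted) cells.  `eem_cube()` stacks several samples measured on a
#' common grid into a `samples x excitation x emission` array.
#'
#' @param ex,em strictly increasing excitation / emission wavelengths (nm).
#' @param intensity numeric matrix `length(ex) x length(em)`.
#' @param mask logical matrix of the same shape, `TRUE` = missing.
#' @return An `eem` / `eem_cube` object.
#' @export
eem <- function(ex, em, intensity, mask = NULL) {
  assert_increasing(ex, "ex")
  assert_increasing(em, "em")
  if (!is.matrix(intensity) || nrow(intensity) != length(ex) ||
      ncol(intensity) != length(em))
    abort_field("intensity", "must be a length(ex) x length(em) matrix")
  if (is.null(mask)) mask <- matrix(FALSE, length(ex), length(em))
  if (!is.logical(mask) || !identical(dim(mask), dim(intensity)))
    abort_field("mask", "must be a logical matrix matching intensity")
  if (any(!is.finite(intensity[!mask])))
    abort_field("intensity", "must be finite on unmasked cells")
  structure(list(ex = as.numeric(ex), em = as.numeric(em),
                 intensity = intensity, mask = mask),
            class = "eem")
}

#' @param intensities numeric array `n_samples x length(ex) x length(em)`.
#' @param sample_ids optional sample identifiers.
#' @rdname eem
#' @export
eem_cube <- function(ex, em, intensities, mask = NULL, sample_ids = NULL) {
  assert_increasing(ex, "ex")
  assert_increasing(em, "em")
  d <- dim(intensities)
  if (length(d) != 3L || d[2] != length(ex) || d[3] != length(em))
    abort_field("intensities", "must be an n x length(ex) x length(em) array")
  if (is.null(mask)) mask <- array(FALSE, d)
  if (!is.logical(mask) || !identical(dim(mask), d))
    abort_field("mask", "must be a logical array matching intensities")
  if (any(!is.finite(intensities[!mask])))
    abort_field("intensities", "must be finite on unmasked cells")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(d[1]))
  structure(list(ex = as.numeric(ex), em = as.numeric(em),
                 intensities = intensities, mask = mask,
                 sample_ids = as.character(sample_ids)),
            class = "eem_cube")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d ex x %d em (%.0f-%.0f / %.0f-%.0f nm), %d masked cells\n",
              length(x$ex), length(x$em), min(x$ex), max(x$ex),
              min(x$em), max(x$em), sum(x$mask)))
  invisible(x)
}

#' @export
print.eem_cube <- function(x, ...) {
  cat(sprintf("<eem_cube> %d samples, %d ex x %d em, %d masked cells/sample grid\n",
              dim(x$intensities)[1], length(x$ex), length(x$em),
              sum(x$mask[1, , ])))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$ex, b$ex)) && isTRUE(all.equal(a$em, b$em))
}

#' Subtract an optical blank from a sample EEM
#'
#' Element-wise subtraction of a Milli-Q blank measured on the identical
#' grid (the standard Raman-scatter correction); masks are propagated by
#' union.
#'
#' @param x sample [eem()].
#' @param blank blank [eem()] on the same grid.
#' @return An [eem()] of differences.
#' @export
subtract_blank <- function(x, blank) {
  stopifnot(inherits(x, "eem"), inherits(blank, "eem"))
  if (!same_grid(x, blank))
    abort_field("blank", "grids of sample and blank must match")
  eem(x$ex, x$em, x$intensity - blank$intensity, x$mask | blank$mask)
}

#' Mask first- and second-order Rayleigh scatter bands
#'
#' Cells with `|em - ex| <= half_width` (first order) or
#' `|em - 2 ex| <= half_width` (second order) are flagged as missing,
#' not interpolated; unmasked intensities are untouched.  Works on a
#' single [eem()] or a whole [eem_cube()].
#'
#' @param x an [eem()] or [eem_cube()].
#' @param half_width band half-width in nm (>= 0), default 10.
#' @return Object of the same class with the scatter cells masked.
#' @export
remove_rayleigh <- function(x, half_width = 10) {
  assert_scalar_number(half_width, "half_width", lower = 0)
  UseMethod("remove_rayleigh")
}

scatter_band_mask <- function(ex, em, half_width) {
  d1 <- abs(outer(ex, em, function(e, m) m - e))
  d2 <- abs(outer(ex, em, function(e, m) m - 2 * e))
  d1 <= half_width | d2 <= half_width
}

#' @export
remove_rayleigh.eem <- function(x, half_width = 10) {
  band <- scatter_band_mask(x$ex, x$em, half_width)
  eem(x$ex, x$em, x$intensity, x$mask | band)
}

#' @export
remove_rayleigh.eem_cube <- function(x, half_width = 10) {
  band <- scatter_band_mask(x$ex, x$em, half_width)
  mask <- x$mask | aperm(array(band, c(dim(band), dim(x$intensities)[1])),
                         c(3, 1, 2))
  eem_cube(x$ex, x$em, x$intensities, mask, x$sample_ids)
}

#' Total (and DOC-normalized) fluorescence of an EEM
#'
#' Sum of all unmasked intensities; when a DOC concentration is given the
#' DOC-normalized total is returned alongside.
#'
#' @param x an [eem()].
#' @param doc optional DOC concentration (mg C/L, > 0).
#' @return The scalar total, or a named vector `c(total, normalized)`
#'   when `doc` is supplied.
#' @export
total_fluorescence <- function(x, doc = NULL) {
  stopifnot(inherits(x, "eem"))
  tot <- sum(x$intensity[!x$mask])
  if (is.null(doc)) return(tot)
  assert_scalar_number(doc, "doc", lower = 0, strict = TRUE)
  c(total = tot, normalized = tot / doc)
}

#' Read or write an EEM as a matrix CSV
#'
#' Layout: first row holds the emission wavelengths, first column the
#' excitation wavelengths, body cells the intensities; missing (masked)
#' cells are written empty.
#'
#' @param x an [eem()].
#' @param path file path.
#' @return `read_eem_csv()` returns an [eem()]; `write_eem_csv()`
#'   returns `path` invisibly.
#' @export
write_eem_csv <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  body <- x$intensity
  body[x$mask] <- NA
  m <- rbind(c(NA, x$em), cbind(x$ex, body))
  utils::write.table(m, path, sep = ",", na = "", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_eem_csv
#' @export
read_eem_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  em <- as.numeric(m[1, -1])
  ex <- as.numeric(m[-1, 1])
  body <- matrix(as.numeric(m[-1, -1]), length(ex), length(em))
  mask <- is.na(body)
  body[mask] <- 0
  eem(ex, em, body, mask)
}

# Extract one sample from a cube as an eem.
cube_sample <- function(cube, i) {
  eem(cube$ex, cube$em, cube$intensities[i, , ], cube$mask[i, , ])
}
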