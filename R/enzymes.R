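ENZYMES <- c("glu", "xyl", "cbh", "nag", "pho", "lip", "pep", "pox")

#' Per-flume extracellular enzyme activity table
#'
#' Potential activities of the eight assayed enzymes per flume:
#' beta-glucosidase (glu), beta-xylosidase (xyl), cellobiohydrolase
#' (cbh), beta-N-acetylglucosaminidase (nag), phosphatase (pho), lipase
#' (lip), leucine-aminopeptidase (pep) and phenol oxidase (pox).
#' Activities are biomass-unnormalized assay rates; only their ratios are
#' biomass-independent.
#'
#' @param flume_id flume identifiers.
#' @param group `"control"` or `"treatment"` per flume.
#' @param activities data.frame (or matrix) with one nonnegative column
#'   per enzyme, named `glu, xyl, cbh, nag, pho, lip, pep, pox`.
#' @return An `enzyme_table` (a `data.frame` subclass).
#' @export
enzyme_table <- function(flume_id, group, activities) {
  group <- as.character(group)
  if (!all(group %in% c("control", "treatment")))
    abort_field("group", "labels must be 'control' or 'treatment'")
  activities <- as.data.frame(activities)
  if (!all(ENZYMES %in% names(activities)))
    abort_field("activities", paste("must contain columns",
                                    paste(ENZYMES, collapse = ", ")))
  activities <- activities[, ENZYMES]
  if (any(!vapply(activities, is.numeric, logical(1))) ||
      any(as.matrix(activities) < 0) || anyNA(activities))
    abort_field("activities", "must be nonnegative and non-missing")
  structure(data.frame(flume_id = as.character(flume_id), group = group,
                       activities, stringsAsFactors = FALSE),
            class = c("enzyme_table", "data.frame"))
}

#' Simulate per-flume enzyme activities
#'
#' Lognormal per-flume activities (lognormal guarantees positivity) with
#' expectation `base_activities` for control flumes and
#' `base_activities * group_multipliers` for treatment flumes, and a
#' common coefficient of variation `cv`.
#'
#' Default base activities are plausible potential-activity magnitudes
#' for stream biofilm assays; default multipliers encode the directions
#' observed in the motivating study (phenol oxidase up, beta-glucosidase
#' down under charcoal addition, hence a lower recalcitrance index).
#'
#' @param base_activities named positive vector over the eight enzymes.
#' @param group_multipliers named positive vector of treatment factors.
#' @param n_per_group flumes per group (default 5).
#' @param cv lognormal coefficient of variation (>= 0), default 0.15.
#' @param seed integer seed.
#' @return An [enzyme_table()] with `2 * n_per_group` rows.
#' @export
simulate_enzyme_plate <- function(
    base_activities = c(glu = 120, xyl = 35, cbh = 20, nag = 60,
                        pho = 300, lip = 80, pep = 150, pox = 40),
    group_multipliers = c(glu = 0.7, xyl = 0.95, cbh = 1.15, nag = 0.9,
                          pho = 1.0, lip = 1.0, pep = 1.0, pox = 1.6),
    n_per_group = 5, cv = 0.15, seed = 1L) {
  if (!all(ENZYMES %in% names(base_activities)))
    abort_field("base_activities", "must name all eight enzymes")
  base_activities <- base_activities[ENZYMES]
  if (any(base_activities <= 0) || anyNA(base_activities))
    abort_field("base_activities", "must be > 0")
  if (!all(ENZYMES %in% names(group_multipliers)))
    abort_field("group_multipliers", "must name all eight enzymes")
  group_multipliers <- group_multipliers[ENZYMES]
  if (any(group_multipliers <= 0) || anyNA(group_multipliers))
    abort_field("group_multipliers", "must be > 0")
  n_per_group <- assert_count(n_per_group, "n_per_group")
  assert_scalar_number(cv, "cv", lower = 0)
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    draw <- function(means) {
      # meanlog chosen so the lognormal expectation equals `means`
      m <- matrix(0, n_per_group, length(means))
      for (e in seq_along(means))
        m[, e] <- stats::rlnorm(n_per_group,
                                meanlog = log(means[e]) - sdlog^2 / 2,
                                sdlog = sdlog)
      colnames(m) <- names(means)
      m
    }
    acts <- rbind(draw(base_activities),
                  draw(base_activities * group_multipliers))
    enzyme_table(
      flume_id = c(sprintf("c_%02d", seq_len(n_per_group)),
                   sprintf("t_%02d", seq_len(n_per_group))),
      group = rep(c("control", "treatment"), each = n_per_group),
      activities = acts)
  })
}

RATIO_DEFS <- list(
  xyl_glu = function(a) a$xyl / a$glu,
  glu_xyl_cbh = function(a) (a$glu + a$xyl) / a$cbh,
  glu_pep = function(a) a$glu / a$pep,
  glu_pox = function(a) a$glu / a$pox,   # recalcitrance index
  pep_pho = function(a) a$pep / a$pho,
  nag_pox = function(a) a$nag / a$pox)

RATIO_DENOMS <- c(xyl_glu = "glu", glu_xyl_cbh = "cbh", glu_pep = "pep",
                  glu_pox = "pox", pep_pho = "pho", nag_pox = "pox")

#' Biomass-independent enzymatic activity ratio indices
#'
#' Computes, per flume, the six ratio indices: `Xyl/Glu` (use of large
#' polymeric carbon), `(Glu+Xyl)/Cbh` (simple vs complex
#' polysaccharides), `Glu/Pep` (glucose vs amino acids as C source),
#' `Glu/Pox` (the recalcitrance index), `Pep/Pho` (N vs P limitation)
#' and `NAG/Pox` (labile C and N vs lignin-derived C).  Ratios with a
#' zero denominator are returned as `NA` with a warning, never as
#' infinities.
#'
#' @param table an [enzyme_table()].
#' @return data.frame with `flume_id`, `group` and one column per ratio.
#' @export
enzyme_ratios <- function(table) {
  if (!inherits(table, "enzyme_table"))
    abort_field("table", "must be an enzyme_table")
  out <- data.frame(flume_id = table$flume_id, group = table$group,
                    stringsAsFactors = FALSE)
  undefined <- character(0)
  for (nm in names(RATIO_DEFS)) {
    bad <- table[[RATIO_DENOMS[[nm]]]] == 0
    v <- RATIO_DEFS[[nm]](table)
    v[bad] <- NA_real_
    if (any(bad)) undefined <- c(undefined, nm)
    out[[nm]] <- v
  }
  if (length(undefined))
    warning("undefined ratios (zero denominator) set to NA: ",
            paste(unique(undefined), collapse = ", "), call. = FALSE)
  out
}

#' Control-versus-treatment t test for one ratio index
#'
#' Paired mode (the default, matching a per-pair-difference design with
#' `df = n - 1`) computes the one-sample t statistic on
#' treatment-minus-control pairwise differences; Welch mode is the
#' unpaired alternative when no pairing is defensible.
#'
#' @param control,treatment numeric ratio values per group (>= 2 each;
#'   equal lengths required for paired mode — flumes are paired by
#'   position).
#' @param mode `"paired"` or `"welch"`.
#' @param ratio_name label carried into the result.
#' @return A `ratio_result` list: `ratio_name`, the group values,
#'   `t_statistic`, `degrees_of_freedom`, `p_value` (two-sided) and
#'   `direction` (`"increase"`/`"decrease"`/`"none"` under treatment).
#' @export
compare_ratios <- function(control, treatment, mode = c("paired", "welch"),
                           ratio_name = "ratio") {
  mode <- match.arg(mode)
  if (!is.numeric(control) || !is.numeric(treatment) ||
      length(control) < 2L || length(treatment) < 2L ||
      anyNA(control) || anyNA(treatment))
    abort_field("control/treatment", "need >= 2 non-missing values per group")
  if (mode == "paired" && length(control) != length(treatment))
    abort_field("mode", "paired mode requires equal group sizes")
  diff_mean <- mean(treatment) - mean(control)
  if (mode == "paired" && stats::sd(treatment - control) == 0) {
    # degenerate: all pairwise differences identical
    t_stat <- if (diff_mean == 0) 0 else sign(diff_mean) * Inf
    df <- length(control) - 1
    p <- if (diff_mean == 0) 1 else 0
  } else {
    tt <- if (mode == "paired")
      stats::t.test(treatment, control, paired = TRUE)
    else
      stats::t.test(treatment, control, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(ratio_name = ratio_name,
                 control_values = control, treatment_values = treatment,
                 t_statistic = t_stat, degrees_of_freedom = df,
                 p_value = p,
                 direction = if (diff_mean > 0) "increase"
                             else if (diff_mean < 0) "decrease" else "none",
                 mode = mode),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> %s (%s): t = %.3f, df = %g, p = %.4f (%s)\n",
              x$ratio_name, x$mode, x$t_statistic, x$degrees_of_freedom,
              x$p_value, x$direction))
  invisible(x)
}

#' Test all six ratio indices between groups
#'
#' @param table an [enzyme_table()].
#' @param mode passed to [compare_ratios()].
#' @return data.frame with one row per ratio: `ratio`, `t`, `df`, `p`,
#'   `direction`.
#' @export
test_enzyme_ratios <- function(table, mode = "paired") {
  ratios <- enzyme_ratios(table)
  ctrl <- ratios[ratios$group == "control", , drop = FALSE]
  trt <- ratios[ratios$group == "treatment", , drop = FALSE]
  rows <- lapply(names(RATIO_DEFS), function(nm) {
    res <- compare_ratios(ctrl[[nm]], trt[[nm]], mode = mode, ratio_name = nm)
    data.frame(ratio = nm, t = res$t_statistic, df = res$degrees_of_freedom,
               p = res$p_value, direction = res$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read or write an enzyme table as CSV
#'
#' Layout: `flume_id, group, glu, xyl, cbh, nag, pho, lip, pep, pox`.
#'
#' @param x an [enzyme_table()].
#' @param path file path.
#' @return `read_enzyme_csv()` returns an `enzyme_table`.
#' @export
write_enzyme_csv <- function(x, path) {
  stopifnot(inherits(x, "enzyme_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enzyme_csv
#' @export
read_enzyme_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  enzyme_table(df$flume_id, df$group, df[, ENZYMES])
}
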