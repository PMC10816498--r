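#' Summarize out-of-range and extrapolated values across a paired study
#'
#' Counts the per-analyte cell statuses in each panel and pools them into a
#' single missing-or-extrapolated fraction per analyte, with denominator
#' 2 x n patients (one plasma and one medium cell per pair). Analytes with
#' every cell measured in both panels form the `complete_analytes` set — the
#' candidate pool for reference-cytokine selection.
#'
#' @param study an [paired_study] object.
#' @return An object of class `xplex_missingness`: list with
#'   `per_specimen` (data.frame: specimen, analyte, n_total, n_measured,
#'   n_extrapolated, n_below, n_above), `pooled` (data.frame: analyte,
#'   n_total, n_missing_or_extrapolated, fraction), and `complete_analytes`.
#' @export
summarize_missingness <- function(study) {
  stopifnot(inherits(study, "xplex_study"))
  per <- lapply(list(study$plasma, study$medium), function(p) {
    cnt <- function(s) colSums(p$status == s)
    data.frame(specimen = p$specimen_type, analyte = p$analytes,
               n_total = nrow(p$status),
               n_measured = cnt("measured"),
               n_extrapolated = cnt("extrapolated"),
               n_below = cnt("below_range"),
               n_above = cnt("above_range"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  agg <- function(col) tapply(per[[col]], per$analyte, sum)[study$plasma$analytes]
  n_total <- agg("n_total")
  n_moe <- agg("n_extrapolated") + agg("n_below") + agg("n_above")
  pooled <- data.frame(analyte = study$plasma$analytes,
                       n_total = as.integer(n_total),
                       n_missing_or_extrapolated = as.integer(n_moe),
                       fraction = as.numeric(n_moe / n_total),
                       row.names = NULL, stringsAsFactors = FALSE)
  complete <- pooled$analyte[pooled$n_missing_or_extrapolated == 0L]
  structure(list(per_specimen = per, pooled = pooled,
                 complete_analytes = complete),
            class = "xplex_missingness")
}

#' @export
print.xplex_missingness <- function(x, ...) {
  cat(sprintf("<xplex_missingness: %d analytes, %d complete (all cells measured in both panels)>\n",
              nrow(x$pooled), length(x$complete_analytes)))
  if (length(x$complete_analytes))
    cat("  complete:", paste(x$complete_analytes, collapse = ", "), "\n")
  cat(sprintf("  pooled missing-or-extrapolated fraction: median %.2f, max %.2f\n",
              stats::median(x$pooled$fraction), max(x$pooled$fraction)))
  invisible(x)
}

substitution_values <- function(panel, lim) {
  d <- panel$dilution_factor
  list(below = lim$llod * d / 2,  # llod/2 for neat medium, llod for 1:1 plasma
       above = lim$ulod * d)     # ulod for medium, 2*ulod for plasma
}

#' Substitution imputation of out-of-range values (quantitative branch)
#'
#' Measured and extrapolated concentrations pass through unchanged. Cells
#' below the detection range are replaced by `llod * dilution_factor / 2`
#' (i.e. LLOD/2 for undiluted conditioned medium, LLOD for 1:1-diluted
#' plasma) and cells above it by `ulod * dilution_factor` (ULOD for medium,
#' 2 x ULOD for plasma).
#'
#' @param panel an [xplex_panel].
#' @param limits an [xplex_limits] table covering the panel's analytes.
#' @return A dense numeric patients x analytes matrix.
#' @export
impute_points <- function(panel, limits) {
  stopifnot(inherits(panel, "xplex_panel"))
  lim <- limits_for(limits, panel$analytes)
  sub <- substitution_values(panel, lim)
  out <- panel$conc
  below <- panel$status == "below_range"
  above <- panel$status == "above_range"
  out[below] <- matrix(sub$below, nrow(out), ncol(out), byrow = TRUE)[below]
  out[above] <- matrix(sub$above, nrow(out), ncol(out), byrow = TRUE)[above]
  if (anyNA(out)) stop("cell with unknown status survived imputation")
  out
}

#' Interval encoding of censored values (qualitative branch)
#'
#' Every fully observed (measured or extrapolated) value `v` becomes the
#' point interval `[v, v]`. Below-range cells become
#' `[0, llod * dilution_factor]` (`[0, LLOD]` for medium, `[0, 2*LLOD]` for
#' plasma) and above-range cells `[ulod * dilution_factor, Inf]`
#' (`[ULOD, Inf]` for medium, `[2*ULOD, Inf]` for plasma).
#'
#' @inheritParams impute_points
#' @return A list with numeric matrices `lo` and `hi` (entries of `hi` may be
#'   `Inf`), both patients x analytes.
#' @export
build_intervals <- function(panel, limits) {
  stopifnot(inherits(panel, "xplex_panel"))
  lim <- limits_for(limits, panel$analytes)
  d <- panel$dilution_factor
  lo <- panel$conc
  hi <- panel$conc
  below <- panel$status == "below_range"
  above <- panel$status == "above_range"
  llod_m <- matrix(lim$llod * d, nrow(lo), ncol(lo), byrow = TRUE)
  ulod_m <- matrix(lim$ulod * d, nrow(lo), ncol(lo), byrow = TRUE)
  lo[below] <- 0; hi[below] <- llod_m[below]
  lo[above] <- ulod_m[above]; hi[above] <- Inf
  if (anyNA(lo) || anyNA(hi)) stop("cell with unknown status survived interval construction")
  list(lo = lo, hi = hi)
}

#' Route analytes to the quantitative or qualitative branch
#'
#' An analyte is compared quantitatively (paired Wilcoxon on imputed,
#' normalized concentrations) when its pooled missing-or-extrapolated
#' fraction is below `threshold`, and qualitatively (interval sign test)
#' otherwise. A fraction exactly at the threshold goes to the qualitative
#' branch: the substitution-imputed values are least trustworthy there, so
#' the interval branch is the conservative choice.
#'
#' @param missingness an `xplex_missingness` object.
#' @param threshold pooled fraction cut-off (default 0.40).
#' @return Named character vector (`"quantitative"`/`"qualitative"`) over
#'   all analytes.
#' @export
route_branches <- function(missingness, threshold = 0.40) {
  stopifnot(inherits(missingness, "xplex_missingness"))
  f <- missingness$pooled$fraction
  out <- ifelse(f < threshold, "quantitative", "qualitative")
  names(out) <- missingness$pooled$analyte
  out
}
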