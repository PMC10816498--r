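#' Divide a concentration matrix by per-sample normalization factors
#'
#' @param mat samples x analytes numeric matrix (imputed, dense).
#' @param nf positive per-sample normalization factors, length `nrow(mat)`.
#' @param drop analyte names to exclude from the output (conventionally the
#'   reference analytes, which would be trivially non-differential).
#' @return Unitless samples x analytes matrix of normalized ratios.
#' @export
normalize_panel <- function(mat, nf, drop = character()) {
  mat <- as.matrix(mat)
  if (length(nf) != nrow(mat)) stop("one normalization factor per sample required")
  if (any(!is.finite(nf)) || any(nf <= 0)) stop("normalization factors must be positive")
  keep <- setdiff(colnames(mat), drop)
  sweep(mat[, keep, drop = FALSE], 1, nf, "/")
}

#' Paired Wilcoxon signed-rank comparison (quantitative branch)
#'
#' Two-sided paired Wilcoxon signed-rank test on normalized concentrations;
#' zero differences are dropped, the exact null distribution is used for
#' small untied samples and the tie/continuity-corrected normal
#' approximation otherwise (the behaviour of [stats::wilcox.test]). The
#' direction is the sign of the median paired difference.
#'
#' @param plasma_norm,medium_norm equal-length paired numeric vectors.
#' @return List with `W` (statistic for `plasma - medium`), `p`, and
#'   `direction` (`"plasma"`, `"medium"`, or `"none"`).
#' @export
wilcoxon_branch <- function(plasma_norm, medium_norm) {
  if (length(plasma_norm) != length(medium_norm)) stop("vectors must be paired")
  d <- plasma_norm - medium_norm
  if (all(d == 0)) return(list(W = 0, p = 1, direction = "none"))
  wt <- suppressWarnings(stats::wilcox.test(plasma_norm, medium_norm,
                                            paired = TRUE, exact = NULL,
                                            correct = TRUE))
  med <- stats::median(d)
  direction <- if (med > 0) "plasma" else if (med < 0) "medium" else "none"
  list(W = unname(wt$statistic), p = wt$p.value, direction = direction)
}

interval_dominance <- function(lo_a, hi_a, lo_b, hi_b) {
  # +1 if [lo_a, hi_a] lies wholly above [lo_b, hi_b], -1 if wholly below,
  # 0 if they intersect (touching endpoints count as intersecting)
  if (lo_a <= hi_b && lo_b <= hi_a) return(0L)
  if (lo_a > hi_b) 1L else -1L
}

#' Exact sign test on paired concentration intervals (qualitative branch)
#'
#' Each pair contributes a comparison of two intervals: intersecting
#' intervals (including touching endpoints) are ties; otherwise the pair
#' counts toward the specimen whose interval lies wholly above. Ties are
#' excluded and the remaining counts are tested with a two-sided exact
#' binomial sign test, `p = min(1, 2 * min(P(X <= min), P(X >= max)))` with
#' `X ~ Binomial(n_plus + n_minus, 1/2)`.
#'
#' @param plasma_int,medium_int interval sets as returned by
#'   [build_intervals] restricted to one analyte: lists with numeric `lo`,
#'   `hi` vectors of equal length (pairs in the same order).
#' @return List with `n_plus` (plasma higher), `n_minus` (medium higher),
#'   `n_tie`, `p`, `direction`.
#' @export
sign_branch <- function(plasma_int, medium_int) {
  lo_p <- plasma_int$lo; hi_p <- plasma_int$hi
  lo_m <- medium_int$lo; hi_m <- medium_int$hi
  n <- length(lo_p)
  if (length(hi_p) != n || length(lo_m) != n || length(hi_m) != n)
    stop("interval vectors must be paired and of equal length")
  if (any(lo_p > hi_p) || any(lo_m > hi_m)) stop("malformed interval: lo > hi")
  dom <- vapply(seq_len(n), function(i)
    interval_dominance(lo_p[i], hi_p[i], lo_m[i], hi_m[i]), 0L)
  n_plus <- sum(dom == 1L); n_minus <- sum(dom == -1L); n_tie <- sum(dom == 0L)
  k <- n_plus + n_minus
  if (k == 0L)
    return(list(n_plus = 0L, n_minus = 0L, n_tie = n_tie, p = 1, direction = "none"))
  lo_tail <- stats::pbinom(min(n_plus, n_minus), k, 0.5)
  hi_tail <- stats::pbinom(max(n_plus, n_minus) - 1L, k, 0.5, lower.tail = FALSE)
  p <- min(1, 2 * min(lo_tail, hi_tail))
  direction <- if (n_plus > n_minus) "plasma" else if (n_minus > n_plus) "medium" else "none"
  list(n_plus = n_plus, n_minus = n_minus, n_tie = n_tie, p = p,
       direction = direction)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1),
#' applied jointly across all non-reference analytes of both branches.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the two-branch paired differential analysis
#'
#' Routes every non-reference analyte by its pooled missing-or-extrapolated
#' fraction: below `missing_threshold` it is imputed ([impute_points]),
#' normalized by the per-sample NF and tested with the paired Wilcoxon
#' signed-rank test; at or above the threshold its cells are encoded as
#' concentration intervals ([build_intervals]), normalized by the NF
#' (both endpoints divided by the sample's factor) and tested with the
#' interval sign test. Raw p-values of both branches are adjusted jointly
#' with Benjamini-Hochberg.
#'
#' @param study an [paired_study] object.
#' @param references reference analyte names (the NF members).
#' @param alpha significance level (default 0.05).
#' @param missing_threshold branch-routing fraction (default 0.40).
#' @return An `xplex_comparison` data.frame: one row per analyte with
#'   columns `analyte`, `branch`, `criterion`, `reference`, `direction`,
#'   `statistic`, `n_plus`, `n_minus`, `n_tie`, `p_raw`, `p_adj`,
#'   `class`, `elevated_in_plasma`, `elevated_in_medium`.
#' @export
compare_study <- function(study, references, alpha = 0.05,
                          missing_threshold = 0.40) {
  stopifnot(inherits(study, "xplex_study"))
  analytes <- study$plasma$analytes
  if (!all(references %in% analytes))
    stop("unknown reference analyte(s): ",
         paste(setdiff(references, analytes), collapse = ", "))
  miss <- summarize_missingness(study)
  branch <- route_branches(miss, missing_threshold)
  targets <- setdiff(analytes, references)

  nfp <- panel_nf(study$plasma, references)
  nfm <- panel_nf(study$medium, references)
  imp_p <- impute_points(study$plasma, study$limits)
  imp_m <- impute_points(study$medium, study$limits)
  int_p <- build_intervals(study$plasma, study$limits)
  int_m <- build_intervals(study$medium, study$limits)

  rows <- lapply(targets, function(a) {
    if (branch[[a]] == "quantitative") {
      r <- wilcoxon_branch(imp_p[, a] / nfp, imp_m[, a] / nfm)
      data.frame(analyte = a, branch = "quantitative", criterion = "Wilcoxon",
                 reference = FALSE, direction = r$direction, statistic = r$W,
                 n_plus = NA_integer_, n_minus = NA_integer_, n_tie = NA_integer_,
                 p_raw = r$p, stringsAsFactors = FALSE)
    } else {
      r <- sign_branch(list(lo = int_p$lo[, a] / nfp, hi = int_p$hi[, a] / nfp),
                       list(lo = int_m$lo[, a] / nfm, hi = int_m$hi[, a] / nfm))
      data.frame(analyte = a, branch = "qualitative", criterion = "Sign",
                 reference = FALSE, direction = r$direction, statistic = NA_real_,
                 n_plus = r$n_plus, n_minus = r$n_minus, n_tie = r$n_tie,
                 p_raw = r$p, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p_raw)
  classify_analytes(tab, references, alpha = alpha)
}

#' Assemble the final per-analyte classification table
#'
#' An analyte is `not_differential` iff its adjusted p exceeds `alpha`;
#' otherwise its class follows the direction of the test. Reference analytes
#' are appended as `not_differential` quantitative rows (they were screened,
#' not re-tested). The per-class counts are attached as the `counts`
#' attribute.
#'
#' @param results data.frame of branch results with columns `analyte`,
#'   `branch`, `criterion`, `direction`, `p_raw`, `p_adj` (plus optional
#'   statistic columns); one row per non-reference analyte.
#' @param references reference analyte names to append.
#' @param alpha significance level (default 0.05).
#' @return The `xplex_comparison` data.frame described in [compare_study],
#'   sorted by analyte name.
#' @export
classify_analytes <- function(results, references = character(), alpha = 0.05) {
  results <- as.data.frame(results)
  if (anyNA(results$p_adj)) stop("analyte(s) with no test result: ",
                                 paste(results$analyte[is.na(results$p_adj)], collapse = ", "))
  cls <- ifelse(results$p_adj > alpha, "not_differential",
                ifelse(results$direction == "plasma", "elevated_in_plasma",
                       ifelse(results$direction == "medium", "elevated_in_medium",
                              "not_differential")))
  results$class <- cls
  if (!"reference" %in% names(results)) results$reference <- FALSE
  if (length(references)) {
    ref_rows <- data.frame(analyte = references, branch = "quantitative",
                           criterion = "Wilcoxon", reference = TRUE,
                           direction = "none", statistic = NA_real_,
                           n_plus = NA_integer_, n_minus = NA_integer_,
                           n_tie = NA_integer_, p_raw = NA_real_,
                           p_adj = NA_real_, class = "not_differential",
                           stringsAsFactors = FALSE)
    for (col in setdiff(names(results), names(ref_rows))) ref_rows[[col]] <- NA
    results <- rbind(results, ref_rows[names(results)])
  }
  results$elevated_in_plasma <- ifelse(results$class == "elevated_in_plasma", "Yes", "No")
  results$elevated_in_medium <- ifelse(results$class == "elevated_in_medium", "Yes", "No")
  results <- results[order(results$analyte), , drop = FALSE]
  rownames(results) <- NULL
  counts <- c(elevated_in_plasma = sum(results$class == "elevated_in_plasma"),
              elevated_in_medium = sum(results$class == "elevated_in_medium"),
              not_differential = sum(results$class == "not_differential"))
  structure(results, counts = counts, alpha = alpha,
            class = c("xplex_comparison", "data.frame"))
}

#' @export
print.xplex_comparison <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("<xplex_comparison: %d analytes; elevated in plasma %d, in medium %d, not differential %d (alpha = %g)>\n",
              nrow(x), counts[["elevated_in_plasma"]],
              counts[["elevated_in_medium"]], counts[["not_differential"]],
              attr(x, "alpha")))
  print.data.frame(x[, c("analyte", "criterion", "elevated_in_plasma",
                         "elevated_in_medium", "p_raw", "p_adj")],
                   digits = 4)
  invisible(x)
}
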