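#' End-to-end analysis of a paired plasma / conditioned-medium study
#'
#' The package's central fitting function. Runs, in order: missingness
#' summary and complete-analyte identification; GeNorm stability ranking of
#' the complete analytes with NF series, V(n/n+1) and NF correlations;
#' the differential-representation screen that settles the reference set
#' (skipped when `references` is pinned by the caller); the two-branch
#' paired differential analysis with joint Benjamini-Hochberg adjustment;
#' and Ward co-regulation clustering of the quantitatively analysable
#' analytes in each specimen type, with a flag when the chosen references
#' co-cluster.
#'
#' @param study an [paired_study] object.
#' @param alpha significance level for screen and classification
#'   (default 0.05).
#' @param missing_threshold pooled missing-or-extrapolated fraction routing
#'   analytes to the qualitative branch (default 0.40).
#' @param references optional pinned reference analytes, bypassing the
#'   automatic screen (useful to reproduce a published choice).
#' @param max_refs cap on the NF series length (default 5).
#' @param cluster_scale `"log2"` (default) or `"raw"`, see [ward_cluster].
#' @param cluster_k optional flat-cluster count, see [cut_tree].
#' @return An object of class `xplex_analysis` with elements `missingness`,
#'   `stability`, `screen` (`NULL` when references were pinned),
#'   `references`, `comparison` (the per-analyte table), `trees`,
#'   `coregulation`, `params`, `call`.
#' @seealso [print.xplex_analysis], [summary.xplex_analysis],
#'   [plot.xplex_analysis]
#' @export
#' @examples
#' sim <- generate_study(study_preset(seed = 42))
#' fit <- analyze_study(sim$study)
#' fit
analyze_study <- function(study, alpha = 0.05, missing_threshold = 0.40,
                          references = NULL, max_refs = 5L,
                          cluster_scale = "log2", cluster_k = NULL) {
  stopifnot(inherits(study, "xplex_study"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(missing_threshold > 0 && missing_threshold < 1))
    stop("missing_threshold must lie in (0, 1)")
  miss <- summarize_missingness(study)
  stab <- if (length(miss$complete_analytes) >= 3)
    stability_report(study, max_refs = max_refs) else NULL
  screen <- NULL
  if (is.null(references)) {
    if (is.null(stab))
      stop("fewer than 3 complete analytes: pin `references` explicitly")
    screen <- reference_screen(study, stab, alpha = alpha)
    references <- screen$references
  }
  comparison <- compare_study(study, references, alpha = alpha,
                              missing_threshold = missing_threshold)
  branch <- route_branches(miss, missing_threshold)
  quant <- names(branch)[branch == "quantitative"]
  trees <- coreg <- NULL
  if (length(quant) >= 2) {
    trees <- list(
      plasma = ward_cluster(impute_points(study$plasma, study$limits),
                            quant, scale = cluster_scale),
      medium = ward_cluster(impute_points(study$medium, study$limits),
                            quant, scale = cluster_scale))
    if (all(references %in% quant))
      coreg <- lapply(trees, coregulation_flag, references = references,
                      k = cluster_k)
  }
  structure(list(missingness = miss, stability = stab, screen = screen,
                 references = references, comparison = comparison,
                 trees = trees, coregulation = coreg,
                 params = list(alpha = alpha,
                               missing_threshold = missing_threshold,
                               max_refs = max_refs,
                               cluster_scale = cluster_scale,
                               cluster_k = cluster_k),
                 call = match.call()),
            class = "xplex_analysis")
}

#' @export
print.xplex_analysis <- function(x, ...) {
  counts <- attr(x$comparison, "counts")
  cat("Paired plasma / conditioned-medium cytokine analysis\n")
  cat(sprintf("  %d paired samples, %d analytes\n",
              x$missingness$pooled$n_total[1] / 2, nrow(x$missingness$pooled)))
  cat(sprintf("  complete analytes (candidate references): %s\n",
              paste(x$missingness$complete_analytes, collapse = ", ")))
  cat(sprintf("  references used: %s%s\n", paste(x$references, collapse = ", "),
              if (is.null(x$screen)) " (pinned)" else " (screened)"))
  cat(sprintf("  elevated in plasma %d, elevated in medium %d, not differential %d (alpha = %g)\n",
              counts[["elevated_in_plasma"]], counts[["elevated_in_medium"]],
              counts[["not_differential"]], x$params$alpha))
  if (!is.null(x$coregulation)) {
    co <- vapply(x$coregulation, `[[`, TRUE, "co_clustered")
    if (any(co))
      cat("  caveat: references co-cluster in", paste(names(co)[co], collapse = " and "),
          "- possible co-regulation\n")
  }
  invisible(x)
}

#' @export
summary.xplex_analysis <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$stability)) {
    cat("\nStability ranking (GeNorm):\n")
    print(x$stability)
  }
  if (!is.null(x$screen)) {
    cat("\nReference screen:\n")
    print(x$screen)
  }
  cat("\nPer-analyte classification:\n")
  print(x$comparison)
  invisible(x)
}

#' Diagnostic plots for an analysis
#'
#' `which = "stability"` draws the NF pairwise variations V(n/n+1) as bars
#' (small bars mean adding another reference changes nothing);
#' `"dendrogram"` draws the Ward trees for both specimen types;
#' `"missingness"` draws the pooled missing-or-extrapolated fraction per
#' analyte with the branch-routing threshold.
#'
#' @param x an `xplex_analysis`.
#' @param which one of `"stability"`, `"dendrogram"`, `"missingness"`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.xplex_analysis <- function(x, which = c("stability", "dendrogram",
                                             "missingness"), ...) {
  which <- match.arg(which)
  if (which == "stability") {
    if (is.null(x$stability)) stop("no stability report in this analysis")
    graphics::barplot(x$stability$V, ylab = "pairwise variation V(n/n+1)",
                      main = "Normalization-factor pairwise variation")
  } else if (which == "dendrogram") {
    if (is.null(x$trees)) stop("no clustering in this analysis")
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    for (nm in names(x$trees))
      plot(x$trees[[nm]]$hclust, main = paste("Ward clustering,", nm),
           xlab = "", sub = "")
  } else {
    f <- x$missingness$pooled
    ord <- order(f$fraction)
    graphics::barplot(f$fraction[ord], names.arg = f$analyte[ord], las = 2,
                      cex.names = 0.6, ylab = "pooled missing/extrapolated fraction")
    graphics::abline(h = x$params$missing_threshold, lty = 2)
  }
  invisible(x)
}
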