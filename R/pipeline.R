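#' Run the full pipeline from files to a report bundle
#'
#' Reads the plasma and medium panels plus the detection limits, validates
#' them, runs [analyze_study], and writes a deterministic report bundle to
#' `out_dir`: `missingness.csv` (pooled fractions), `stability_M.csv`,
#' `stability_V.csv`, `nf_correlation.csv`, `screen.csv`,
#' `comparison.csv` (the final per-analyte table),
#' `cluster_<specimen>.nwk` Newick dendrograms, and `manifest.json`
#' recording input checksums, the configuration echo and the package
#' version. Identical inputs and configuration yield byte-identical
#' outputs.
#'
#' @param plasma,medium,limits input file paths (see [read_panel],
#'   [read_limits]).
#' @param out_dir output directory, created if needed.
#' @param dialect panel dialect, `"wide"` or `"long"`.
#' @param alpha,missing_threshold,references,max_refs,cluster_scale,cluster_k
#'   passed to [analyze_study].
#' @return The `xplex_analysis` object, invisibly.
#' @export
run_pipeline <- function(plasma, medium, limits, out_dir,
                         dialect = "wide", alpha = 0.05,
                         missing_threshold = 0.40, references = NULL,
                         max_refs = 5L, cluster_scale = "log2",
                         cluster_k = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  study <- stage("read", {
    p <- read_panel(plasma, "plasma", dialect)
    m <- read_panel(medium, "medium", dialect)
    l <- read_limits(limits, analytes = p$analytes)
    paired_study(p, m, l)
  })
  stage("validate", {
    issues <- validate_study(study)
    if (nrow(issues))
      warning(nrow(issues), " cell(s) inconsistent with the detection limits; ",
              "see validate_study() for details")
  })
  fit <- stage("analyze",
    analyze_study(study, alpha = alpha, missing_threshold = missing_threshold,
                  references = references, max_refs = max_refs,
                  cluster_scale = cluster_scale, cluster_k = cluster_k))
  stage("report", write_bundle(fit, out_dir,
                               inputs = c(plasma = plasma, medium = medium,
                                          limits = limits)))
  invisible(fit)
}

write_bundle <- function(fit, out_dir, inputs = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(fit$missingness$pooled, "missingness.csv")
  if (!is.null(fit$stability)) {
    gen <- fit$stability$genorm
    wcsv(data.frame(analyte = names(gen$M_full), M = as.numeric(gen$M_full),
                    rank = match(names(gen$M_full), gen$ranking)),
         "stability_M.csv")
    wcsv(data.frame(step = names(fit$stability$V),
                    V = as.numeric(fit$stability$V)), "stability_V.csv")
    corr <- as.data.frame(fit$stability$nf_corr)
    corr <- cbind(factor_ = rownames(fit$stability$nf_corr), corr)
    wcsv(corr, "nf_correlation.csv")
  }
  if (!is.null(fit$screen))
    wcsv(do.call(rbind, lapply(seq_along(fit$screen$rounds), function(i)
      cbind(round = i, fit$screen$rounds[[i]]))), "screen.csv")
  write_comparison_table(fit$comparison, file.path(out_dir, "comparison.csv"))
  for (nm in names(fit$trees))
    write_tree_newick(fit$trees[[nm]], file.path(out_dir, paste0("cluster_", nm, ".nwk")))
  manifest <- list(
    package = "xplexnorm",
    version = as.character(utils::packageVersion("xplexnorm")),
    inputs = if (length(inputs))
      lapply(inputs, function(f) list(path = f, md5 = unname(tools::md5sum(f))))
      else NULL,
    params = fit$params,
    references = fit$references,
    counts = as.list(attr(fit$comparison, "counts")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
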