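#' Relative expression by the delta-Ct method
#'
#' For every (sample, population) the target's threshold cycle is normalized
#' to the reference gene measured in the same sample:
#' `rel = 2^-(ct_target - ct_reference)`. A target the instrument never
#' called (undetected, `NA` Ct) is assigned a configurable floor value and
#' flagged `detect = FALSE`. The floor should sit at least two-fold below
#' the smallest detected relative value; a warning is issued otherwise.
#'
#' @param measurements data.frame with columns `sample`, `population`,
#'   `gene`, `ct` (`NA` = undetected). Ct values must lie in (0, 45].
#' @param reference_gene name of the reference gene (default `"UBC"`); its
#'   Ct must be present for every (sample, population) that contributes a
#'   target measurement.
#' @param floor substitute relative value for undetected targets
#'   (default `1e-4`).
#' @return data.frame with columns `sample`, `population`, `gene`,
#'   `delta_ct`, `rel`, `detect`, one row per target measurement.
#' @export
relative_expression <- function(measurements, reference_gene = "UBC",
                                floor = 1e-4) {
  need <- c("sample", "population", "gene", "ct")
  if (!all(need %in% colnames(measurements)))
    stop("measurements must have columns ", paste(need, collapse = ", "))
  m <- measurements
  ok_ct <- is.na(m$ct) | (m$ct > 0 & m$ct <= 45)
  if (!all(ok_ct))
    stop("Ct values must lie in (0, 45] or be NA (undetected)")
  key <- paste(m$sample, m$population, sep = "\r")
  is_ref <- m$gene == reference_gene
  ref_ct <- stats::setNames(m$ct[is_ref], key[is_ref])
  targ <- m[!is_ref, , drop = FALSE]
  tkey <- key[!is_ref]
  miss <- unique(tkey[!(tkey %in% names(ref_ct)) | is.na(ref_ct[tkey])])
  if (length(miss))
    stop("missing reference-gene Ct for sample/population: ",
         paste(sub("\r", " / ", miss), collapse = ", "))
  delta <- targ$ct - ref_ct[tkey]
  rel <- 2^(-delta)
  detect <- !is.na(targ$ct)
  rel[!detect] <- floor
  out <- data.frame(sample = targ$sample, population = targ$population,
                    gene = targ$gene, delta_ct = as.numeric(delta),
                    rel = as.numeric(rel), detect = detect,
                    row.names = NULL, stringsAsFactors = FALSE)
  min_det <- suppressWarnings(min(out$rel[out$detect]))
  if (is.finite(min_det) && floor > min_det / 2)
    warning(sprintf("floor %g is not at least two-fold below the smallest detected relative value (%g)",
                    floor, min_det))
  out
}

#' Delta-delta-Ct expression relative to a calibrator population
#'
#' Rescales [relative_expression] output so that each sample's calibrator
#' population sits at 1: `rel_ddct = 2^-(dCt - dCt_calibrator)`, computed per
#' (sample, gene). Undetected cells keep their floored value divided by the
#' calibrator, with `detect = FALSE` preserved.
#'
#' @param rel output of [relative_expression].
#' @param calibrator population label used as the per-sample calibrator.
#' @return The same data.frame with `rel` rescaled and a `calibrator` column.
#' @export
calibrate_expression <- function(rel, calibrator) {
  base <- rel[rel$population == calibrator, , drop = FALSE]
  if (!nrow(base)) stop("no measurements for calibrator population ", calibrator)
  key <- function(d) paste(d$sample, d$gene, sep = "\r")
  cal <- stats::setNames(base$rel, key(base))
  k <- key(rel)
  miss <- unique(k[!(k %in% names(cal))])
  if (length(miss))
    stop("missing calibrator value for sample/gene: ",
         paste(sub("\r", " / ", miss), collapse = ", "))
  out <- rel
  out$rel <- rel$rel / cal[k]
  out$calibrator <- calibrator
  out
}

#' Paired comparison of a gene's relative expression between two populations
#'
#' Two-sided paired Wilcoxon signed-rank test on relative expression values
#' (floored undetected values included, as in the source analysis); samples
#' without both members of the pair are excluded with a warning.
#'
#' @param rel output of [relative_expression].
#' @param gene gene to compare.
#' @param groups length-2 character vector of population labels, compared as
#'   `groups[1]` vs `groups[2]`.
#' @return List with `n` (pairs used), `p`, `direction` (`groups[1]`,
#'   `groups[2]`, or `"none"`).
#' @export
compare_tissues <- function(rel, gene, groups) {
  stopifnot(length(groups) == 2)
  a <- rel[rel$gene == gene & rel$population == groups[1], , drop = FALSE]
  b <- rel[rel$gene == gene & rel$population == groups[2], , drop = FALSE]
  common <- intersect(a$sample, b$sample)
  dropped <- setdiff(union(a$sample, b$sample), common)
  if (length(dropped))
    warning("unpaired sample(s) excluded: ", paste(dropped, collapse = ", "))
  if (length(common) < 1) stop("no paired samples for gene ", gene)
  x <- a$rel[match(common, a$sample)]
  y <- b$rel[match(common, b$sample)]
  r <- wilcoxon_branch(x, y)
  direction <- switch(r$direction, plasma = groups[1], medium = groups[2], "none")
  list(n = length(common), p = r$p, direction = direction)
}

#' Population x sample expression grid for one gene
#'
#' The heatmap-ready export: relative expression values with undetected
#' cells preserved as flags (no imputation beyond the floor already applied).
#'
#' @param rel output of [relative_expression].
#' @param gene gene to tabulate.
#' @return List with numeric matrix `rel` (populations x samples) and logical
#'   matrix `detect` of the same shape; absent combinations are `NA`.
#' @export
expression_heatmap_table <- function(rel, gene) {
  r <- rel[rel$gene == gene, , drop = FALSE]
  pops <- unique(r$population)
  samples <- unique(r$sample)
  relm <- matrix(NA_real_, length(pops), length(samples),
                 dimnames = list(pops, samples))
  det <- matrix(NA, length(pops), length(samples),
                dimnames = list(pops, samples))
  i <- match(r$population, pops); j <- match(r$sample, samples)
  relm[cbind(i, j)] <- r$rel
  det[cbind(i, j)] <- r$detect
  list(rel = relm, detect = det)
}

#' Write / read a heatmap grid preserving detect flags
#'
#' Undetected cells are written as `ND:<floor value>` so the round trip is
#' lossless.
#'
#' @param grid output of [expression_heatmap_table].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a grid list (reader).
#' @export
write_heatmap_table <- function(grid, path) {
  cells <- matrix(ifelse(is.na(grid$rel), "",
                         ifelse(grid$detect,
                                format(grid$rel, digits = 15, trim = TRUE),
                                paste0("ND:", format(grid$rel, digits = 15, trim = TRUE)))),
                  nrow = nrow(grid$rel), dimnames = dimnames(grid$rel))
  df <- data.frame(population = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_table
#' @export
read_heatmap_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  pops <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  rel <- matrix(NA_real_, nrow(cells), ncol(cells),
                dimnames = list(pops, colnames(cells)))
  det <- matrix(NA, nrow(cells), ncol(cells),
                dimnames = list(pops, colnames(cells)))
  nd <- startsWith(cells, "ND:")
  filled <- !is.na(cells) & nzchar(cells)
  rel[filled & nd] <- as.numeric(substring(cells[filled & nd], 4L))
  rel[filled & !nd] <- as.numeric(cells[filled & !nd])
  det[filled] <- !nd[filled]
  list(rel = rel, detect = det)
}
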