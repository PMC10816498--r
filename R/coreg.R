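#' Ward clustering of analytes within one specimen type
#'
#' Agglomerative clustering of analyte profiles (one observation per
#' analyte, one coordinate per sample) with the Ward minimum-variance
#' criterion, used to flag possible co-regulation: analytes merging early
#' rise and fall together across patients. Clustering runs on the
#' *unnormalized* panel to avoid circularity with the reference-based
#' normalization; concentrations are log2-transformed by default so that
#' distances reflect fold changes rather than absolute abundance.
#'
#' @param mat dense samples x analytes concentration matrix (use
#'   [impute_points] first); restrict `analytes` to the quantitatively
#'   analysable subset.
#' @param analytes analyte names to cluster (>= 2); default all columns.
#' @param scale `"log2"` (default) or `"raw"` input scale.
#' @return An object of class `xplex_tree`: list with `hclust` (a
#'   [stats::hclust] with Ward linkage on Euclidean distances), `analytes`,
#'   `scale`.
#' @export
ward_cluster <- function(mat, analytes = colnames(mat), scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) stop("matrix must carry analyte column names")
  if (length(analytes) < 2) stop("need at least 2 analytes to cluster")
  if (!all(analytes %in% colnames(mat)))
    stop("unknown analyte(s): ", paste(setdiff(analytes, colnames(mat)), collapse = ", "))
  x <- t(mat[, analytes, drop = FALSE])
  if (scale == "log2") {
    if (any(x <= 0)) stop("log2 scale requires strictly positive concentrations")
    x <- log2(x)
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  structure(list(hclust = hc, analytes = analytes, scale = scale),
            class = "xplex_tree")
}

#' @export
print.xplex_tree <- function(x, ...) {
  cat(sprintf("<xplex_tree: Ward clustering of %d analytes (%s scale)>\n",
              length(x$analytes), x$scale))
  cat("  merge heights:", paste(sprintf("%.3g", x$hclust$height), collapse = ", "), "\n")
  invisible(x)
}

#' Flat clusters at a data-driven or user-chosen cut
#'
#' With `k` unspecified, the tree is cut at the largest gap between
#' consecutive merge heights (the natural "elbow"), which leaves the
#' tightly merging groups intact and separates the late, expensive merges.
#'
#' @param tree an `xplex_tree`.
#' @param k optional number of flat clusters overriding the gap heuristic.
#' @return Named integer vector of cluster memberships.
#' @export
cut_tree <- function(tree, k = NULL) {
  stopifnot(inherits(tree, "xplex_tree"))
  hc <- tree$hclust
  n <- length(tree$analytes)
  if (is.null(k)) {
    h <- hc$height
    if (length(h) < 2) k <- 2L
    else {
      gaps <- diff(h)
      # cutting just below the merge after the largest gap keeps n - i clusters
      i <- which.max(gaps)
      k <- n - i
    }
  }
  k <- max(1L, min(as.integer(k), n))
  stats::cutree(hc, k = k)
}

#' Flag whether the reference analytes co-cluster
#'
#' Co-clustered references hint at co-regulation, which can inflate their
#' apparent stability; the analysis proceeds but the caveat is reported.
#'
#' @param tree an `xplex_tree`.
#' @param references analyte names; must all be leaves of the tree.
#' @param k optional flat-cluster count passed to [cut_tree].
#' @return List with `co_clustered` (logical), `k` (clusters used),
#'   `membership` (named vector), `reference_clusters` (memberships of the
#'   references).
#' @export
coregulation_flag <- function(tree, references, k = NULL) {
  stopifnot(inherits(tree, "xplex_tree"))
  missing_refs <- setdiff(references, tree$analytes)
  if (length(missing_refs))
    stop("reference(s) not among clustered analytes: ",
         paste(missing_refs, collapse = ", "))
  membership <- cut_tree(tree, k)
  ref_cl <- membership[references]
  list(co_clustered = length(unique(ref_cl)) == 1L,
       k = length(unique(membership)),
       membership = membership,
       reference_clusters = ref_cl)
}

#' Export a dendrogram in Newick format
#'
#' @param tree an `xplex_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "xplex_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
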