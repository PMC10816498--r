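#' Pairwise variation between two analytes
#'
#' The GeNorm building block: the sample standard deviation (n - 1
#' denominator) of the elementwise log2 concentration ratios. It is zero when
#' the two analytes are strictly proportional across samples and grows as
#' their ratio varies.
#'
#' @param x,y strictly positive numeric vectors of equal length >= 2
#'   (concentrations of two analytes over the same samples).
#' @return A nonnegative unitless number.
#' @export
pairwise_variation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 samples")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("pairwise variation requires strictly positive finite concentrations")
  stats::sd(log2(x / y))
}

m_values <- function(mat) {
  # mean over k != j of pairwise_variation(col_j, col_k)
  k <- ncol(mat)
  lg <- log2(mat)
  vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j),
                function(l) stats::sd(lg[, j] - lg[, l]), 0))
  }, 0)
}

#' GeNorm stability ranking of candidate reference analytes
#'
#' For each candidate, the average stability M is the arithmetic mean of its
#' pairwise variations with every other candidate. The classic stepwise
#' exclusion then repeatedly removes the candidate with the highest M and
#' recomputes M among the remainder, until two candidates are left; these
#' form the most stable pair, within which neither member outranks the other.
#' Ties in the maximal M are broken by input column order (a warning is
#' recorded in the report).
#'
#' @param concentrations strictly positive samples x candidates matrix with
#'   candidate names as column names; samples are conventionally pooled from
#'   both specimen panels.
#' @return An object of class `xplex_genorm`: list with `ranking` (most to
#'   least stable; the first two are the unordered top pair), `top_pair`,
#'   `M_full` (M on the full candidate set, named), `steps` (per-step M
#'   tables), `ties` (character vector of tie notes).
#' @export
genorm_rank <- function(concentrations) {
  mat <- as.matrix(concentrations)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("C", seq_len(ncol(mat)))
  if (ncol(mat) < 3) stop("stepwise exclusion needs at least 3 candidates")
  if (nrow(mat) < 2) stop("need at least 2 samples")
  if (any(!is.finite(mat)) || any(mat <= 0))
    stop("candidate concentrations must be strictly positive and finite")
  M_full <- stats::setNames(m_values(mat), colnames(mat))
  cur <- mat
  excluded <- character()
  steps <- list()
  ties <- character()
  while (ncol(cur) > 2) {
    M <- stats::setNames(m_values(cur), colnames(cur))
    steps[[length(steps) + 1L]] <- M
    worst <- which(M == max(M))
    if (length(worst) > 1L) {
      ties <- c(ties, paste0("max-M tie among {",
                             paste(names(M)[worst], collapse = ", "),
                             "}; broken by input order"))
      worst <- worst[1L]
    } else worst <- which.max(M)
    excluded <- c(excluded, colnames(cur)[worst])
    cur <- cur[, -worst, drop = FALSE]
  }
  M_last <- stats::setNames(m_values(cur), colnames(cur))
  steps[[length(steps) + 1L]] <- M_last
  ranking <- c(colnames(cur), rev(excluded))
  structure(list(ranking = ranking, top_pair = colnames(cur),
                 M_full = M_full, steps = steps, ties = ties),
            class = "xplex_genorm")
}

#' @export
print.xplex_genorm <- function(x, ...) {
  cat("<xplex_genorm>\n  ranking (most -> least stable):",
      paste(x$ranking, collapse = " > "), "\n")
  cat("  top pair (unordered):", paste(sort(x$top_pair), collapse = " & "), "\n")
  cat("  M (full set):",
      paste(sprintf("%s=%.3f", names(x$M_full), x$M_full), collapse = ", "), "\n")
  if (length(x$ties)) cat("  note:", paste(x$ties, collapse = "; "), "\n")
  invisible(x)
}

geometric_mean_rows <- function(mat) {
  mat <- as.matrix(mat)
  exp(rowMeans(log(mat)))
}

#' Per-sample normalization factor from the top-n ranked candidates
#'
#' NFn for a sample is the geometric mean of the concentrations of the n most
#' stable candidates in that sample; samples are later divided by it.
#'
#' @param concentrations samples x candidates positive matrix (named columns).
#' @param ranking candidate names, most to least stable (see [genorm_rank]).
#' @param n how many top candidates enter the factor (1 <= n <= length(ranking)).
#' @return Named numeric vector of per-sample factors (pg/mL).
#' @export
normalization_factors <- function(concentrations, ranking, n) {
  mat <- as.matrix(concentrations)
  if (n < 1 || n > length(ranking)) stop("n out of range 1..", length(ranking))
  use <- ranking[seq_len(n)]
  if (!all(use %in% colnames(mat))) stop("ranking names absent from matrix")
  if (any(mat[, use] <= 0)) stop("nonpositive concentration in normalization candidates")
  stats::setNames(geometric_mean_rows(mat[, use, drop = FALSE]), rownames(mat))
}

#' Pairwise variation between consecutive normalization factors
#'
#' V(n/n+1) = sd of log2(NFn / NFn+1) over samples, the GeNorm criterion for
#' how many references are enough: a small V(n/n+1) means adding the
#' (n+1)-th candidate leaves the factor essentially unchanged.
#'
#' @param nf_series named list of per-sample NF vectors, element `"NF1"` ...;
#'   all on identical samples.
#' @return Named vector `V(1/2)`, `V(2/3)`, ... of length `length(nf_series) - 1`.
#' @export
nf_pairwise_variation <- function(nf_series) {
  k <- length(nf_series)
  if (k < 2) stop("need at least two consecutive normalization factors")
  nms <- lapply(nf_series, names)
  for (i in seq_len(k - 1))
    if (!identical(nms[[i]], nms[[i + 1]]))
      stop("normalization factors computed on mismatched sample sets")
  v <- vapply(seq_len(k - 1), function(n)
    pairwise_variation(nf_series[[n]], nf_series[[n + 1]]), 0)
  stats::setNames(v, paste0("V(", seq_len(k - 1), "/", seq_len(k - 1) + 1, ")"))
}

#' Spearman correlation of normalization factors and single candidates
#'
#' @param nf_series named list of per-sample NF vectors (`NF2` upward).
#' @param singles named list of per-sample single-candidate concentration
#'   vectors (typically the two members of the top stability pair).
#' @return Symmetric Spearman correlation matrix; entries involving a
#'   constant vector are `NA` (undefined) with a warning.
#' @export
nf_correlation <- function(nf_series, singles = list()) {
  vecs <- c(singles, nf_series)
  if (length(vecs) < 2) stop("need at least two vectors to correlate")
  nms <- lapply(vecs, names)
  for (i in seq_along(vecs)[-1])
    if (!identical(nms[[1]], nms[[i]])) stop("vectors on mismatched sample sets")
  m <- do.call(cbind, vecs)
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  out <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant vector(s): ", paste(colnames(m)[const], collapse = ", "),
            "; their correlations are undefined")
    out[const, ] <- NA_real_
    out[, const] <- NA_real_
    diag(out)[!const] <- 1
  }
  out
}

#' Full stability report for the candidate reference analytes
#'
#' Pools the plasma and medium samples of the complete analytes (every cell
#' measured, so no imputation is involved), runs the GeNorm ranking, and
#' derives the NF series, the consecutive pairwise variations V(n/n+1), and
#' the Spearman correlation matrix over the top-pair singles and NF2..NFK.
#'
#' @param study an [paired_study] object.
#' @param candidates analyte names to rank; defaults to the complete set from
#'   [summarize_missingness].
#' @param max_refs cap on the NF series length (default 5).
#' @return An object of class `xplex_stability`: list with `candidates`,
#'   `genorm` (see [genorm_rank]), `nf_series`, `V`, `nf_corr`,
#'   `pooled` (the samples x candidates matrix used; sample names are
#'   `<patient>.plasma` / `<patient>.medium`).
#' @export
stability_report <- function(study, candidates = NULL, max_refs = 5L) {
  stopifnot(inherits(study, "xplex_study"))
  if (is.null(candidates)) {
    candidates <- summarize_missingness(study)$complete_analytes
    if (length(candidates) < 3)
      stop("fewer than 3 complete analytes; supply candidates explicitly")
  }
  pooled <- pool_candidate_matrix(study, candidates)
  gen <- genorm_rank(pooled)
  K <- min(length(candidates), max_refs)
  nf_series <- lapply(seq_len(K), function(n)
    normalization_factors(pooled, gen$ranking, n))
  names(nf_series) <- paste0("NF", seq_len(K))
  V <- nf_pairwise_variation(nf_series)
  singles <- lapply(gen$top_pair, function(a) stats::setNames(pooled[, a], rownames(pooled)))
  names(singles) <- gen$top_pair
  corr <- nf_correlation(nf_series[-1], singles)
  structure(list(candidates = candidates, genorm = gen, nf_series = nf_series,
                 V = V, nf_corr = corr, pooled = pooled),
            class = "xplex_stability")
}

pool_candidate_matrix <- function(study, candidates) {
  miss <- summarize_missingness(study)
  not_complete <- setdiff(candidates, miss$complete_analytes)
  if (length(not_complete))
    warning("candidate(s) with out-of-range or extrapolated cells: ",
            paste(not_complete, collapse = ", "),
            "; stability is computed on measured values only if dense, otherwise this will error")
  p <- study$plasma$conc[, candidates, drop = FALSE]
  m <- study$medium$conc[, candidates, drop = FALSE]
  if (anyNA(p) || anyNA(m))
    stop("candidate analytes must be dense (no out-of-range cells)")
  rownames(p) <- paste0(study$plasma$patients, ".plasma")
  rownames(m) <- paste0(study$medium$patients, ".medium")
  rbind(p, m)
}

#' @export
print.xplex_stability <- function(x, ...) {
  cat("<xplex_stability>\n")
  print(x$genorm)
  cat("  ", paste(sprintf("%s=%.3f", names(x$V), x$V), collapse = ", "), "\n")
  best <- which.min(x$V)
  cat(sprintf("  smallest V at %s -> NF%d suffices by the V criterion\n",
              names(x$V)[best], best))
  invisible(x)
}

#' Screen candidate references for differential representation
#'
#' A valid reference must not differ between plasma and medium after
#' normalization. Starting from the V-optimal NF member set (the n of the
#' smallest V(n/n+1)), each member is normalized by the current NF and
#' compared between the two specimens with the paired Wilcoxon signed-rank
#' test; p-values are Benjamini-Hochberg adjusted across the members
#' screened in that round. If any member is differential (adjusted p <=
#' alpha), the *least stable* differential member (by the GeNorm ranking) is
#' dropped, the NF is rebuilt and the screen repeated, until all remaining
#' members pass or only one is left.
#'
#' @param study an [paired_study] object.
#' @param stability an `xplex_stability` report for the study.
#' @param alpha significance level for the screen (default 0.05).
#' @param start_n initial NF size; defaults to the V-optimal n.
#' @return An object of class `xplex_screen`: list with `references` (final
#'   member set), `nf_plasma`, `nf_medium` (per-patient factors), `rounds`
#'   (per-round data.frame of member, p_raw, p_adj, differential), `start_n`.
#' @export
reference_screen <- function(study, stability, alpha = 0.05, start_n = NULL) {
  stopifnot(inherits(study, "xplex_study"), inherits(stability, "xplex_stability"))
  ranking <- stability$genorm$ranking
  if (is.null(start_n)) start_n <- which.min(stability$V)
  start_n <- max(2L, min(as.integer(start_n), length(ranking)))
  members <- ranking[seq_len(start_n)]
  rounds <- list()
  repeat {
    nfp <- panel_nf(study$plasma, members)
    nfm <- panel_nf(study$medium, members)
    res <- lapply(members, function(a) {
      x <- study$plasma$conc[, a] / nfp
      y <- study$medium$conc[, a] / nfm
      wilcoxon_branch(x, y)
    })
    p_raw <- vapply(res, function(r) r$p, 0)
    p_adj <- bh_adjust(p_raw)
    df <- data.frame(member = members, p_raw = p_raw, p_adj = p_adj,
                     differential = p_adj <= alpha,
                     row.names = NULL, stringsAsFactors = FALSE)
    rounds[[length(rounds) + 1L]] <- df
    if (!any(df$differential) || length(members) == 1L) break
    diff_members <- df$member[df$differential]
    # drop the least stable differential member, one per round
    drop <- diff_members[which.max(match(diff_members, ranking))]
    members <- setdiff(members, drop)
    if (!length(members))
      stop("no candidate reference survives the screen; choose references manually")
  }
  if (length(members) == 1L && any(rounds[[length(rounds)]]$differential))
    stop("no candidate reference survives the screen; choose references manually")
  structure(list(references = members,
                 nf_plasma = panel_nf(study$plasma, members),
                 nf_medium = panel_nf(study$medium, members),
                 rounds = rounds, start_n = start_n),
            class = "xplex_screen")
}

panel_nf <- function(panel, refs) {
  mat <- panel$conc[, refs, drop = FALSE]
  if (anyNA(mat) || any(mat <= 0))
    stop("reference analytes must be strictly positive and dense in panel ",
         panel$specimen_type)
  stats::setNames(geometric_mean_rows(mat), panel$patients)
}

#' @export
print.xplex_screen <- function(x, ...) {
  cat(sprintf("<xplex_screen: started from NF%d, %d round(s)>\n",
              x$start_n, length(x$rounds)))
  cat("  final references:", paste(x$references, collapse = ", "), "\n")
  last <- x$rounds[[length(x$rounds)]]
  cat("  final round adjusted p:",
      paste(sprintf("%s=%.3g", last$member, last$p_adj), collapse = ", "), "\n")
  invisible(x)
}
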