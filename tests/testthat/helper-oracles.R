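# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive each quantity from first principles and share
# no code with the package implementation.

# Exact two-sided paired signed-rank p-value by enumeration of all 2^n sign
# assignments of the nonzero differences (untied data only).
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_w <- as.vector(signs %*% r)
  p <- 2 * min(mean(null_w <= w_obs), mean(null_w >= w_obs))
  min(1, p)
}

# Exact two-sided binomial sign-test p, from the binomial pmf directly.
oracle_sign_p <- function(n_plus, n_minus) {
  k <- n_plus + n_minus
  if (k == 0) return(1)
  pmf <- choose(k, 0:k) / 2^k
  lo <- sum(pmf[seq_len(min(n_plus, n_minus) + 1)])
  hi <- sum(pmf[(max(n_plus, n_minus) + 1):(k + 1)])
  min(1, 2 * min(lo, hi))
}

# Brute-force GeNorm: naive pairwise sd of log2 ratios, arithmetic-mean M,
# stepwise exclusion of the max-M candidate (first index on ties).
oracle_genorm_ranking <- function(mat) {
  pv <- function(a, b) stats::sd(log2(a / b))
  m_of <- function(cols) {
    vapply(seq_along(cols), function(j) {
      others <- cols[-j]
      mean(vapply(others, function(o) pv(mat[, cols[j]], mat[, o]), 0))
    }, 0)
  }
  cols <- colnames(mat)
  excluded <- character()
  while (length(cols) > 2) {
    M <- m_of(cols)
    worst <- which(M == max(M))[1]
    excluded <- c(excluded, cols[worst])
    cols <- cols[-worst]
  }
  c(cols, rev(excluded))
}

# O(n^3) Ward agglomeration minimizing the increase in total within-cluster
# sum of squares; returns the sequence of partitions (canonical form) after
# each merge.
oracle_ward_partitions <- function(X) {
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  out <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      cost <- ess(c(clusters[[a]], clusters[[b]])) -
        ess(clusters[[a]]) - ess(clusters[[b]])
      if (cost < best_cost) { best_cost <- cost; best <- c(a, b) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    out[[length(out) + 1L]] <- canonical_partition(clusters)
  }
  out
}

canonical_partition <- function(clusters) {
  parts <- lapply(clusters, sort)
  parts <- parts[order(vapply(parts, `[`, 0, 1))]
  paste(vapply(parts, paste, "", collapse = ","), collapse = "|")
}

# Partition sequence of an hclust object, for comparison with the oracle.
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  clusters <- as.list(seq_len(n))
  nodes <- list()
  out <- list()
  for (i in seq_len(nrow(hc$merge))) {
    get_members <- function(v) if (v < 0) -v else nodes[[v]]
    members <- sort(c(get_members(hc$merge[i, 1]), get_members(hc$merge[i, 2])))
    nodes[[i]] <- members
    clusters <- Filter(function(cl) !all(cl %in% members), clusters)
    clusters <- c(clusters, list(members))
    out[[i]] <- canonical_partition(clusters)
  }
  out
}

# Compact builders for hand-made fixtures.
make_panel <- function(specimen, conc, status = NULL, dilution = NULL) {
  conc <- as.matrix(conc)
  if (is.null(status))
    status <- matrix("measured", nrow(conc), ncol(conc))
  if (is.null(rownames(conc))) rownames(conc) <- paste0("P", seq_len(nrow(conc)))
  if (is.null(colnames(conc))) colnames(conc) <- paste0("A", seq_len(ncol(conc)))
  if (is.null(dilution)) dilution <- if (specimen == "plasma") 2 else 1
  xplex_panel(specimen, conc, status, dilution_factor = dilution)
}

make_limits <- function(analytes, llod = 0.001, ulod = 1e7) {
  xplex_limits(analytes, rep_len(llod, length(analytes)),
               rep_len(ulod, length(analytes)))
}
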