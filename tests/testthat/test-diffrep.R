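test_that("normalization divides by per-sample factors and round-trips", {
  mat <- matrix(c(10, 20, 4, 8), 2, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  nf <- c(2, 4)
  norm <- normalize_panel(mat, nf)
  expect_equal(norm["s1", "A"], 5)
  expect_equal(sweep(norm, 1, nf, "*"), mat)
  # an analyte identical to the NF normalizes to all ones
  expect_equal(unname(normalize_panel(mat[, "A", drop = FALSE], mat[, "A"])[, 1]),
               c(1, 1))
  expect_equal(colnames(normalize_panel(mat, nf, drop = "A")), "B")
  expect_error(normalize_panel(mat, c(0, 1)), "positive")
})

test_that("the quantitative branch matches exact enumeration and handles degeneracy", {
  expect_equal(wilcoxon_branch(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(wilcoxon_branch(c(1, 2, 3), c(1, 2, 3))$direction, "none")
  r <- wilcoxon_branch(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(r$p, 0.0625)  # 2/2^5, all five differences positive
  expect_equal(r$direction, "plasma")
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:10, 1)
    x <- rlnorm(n); y <- rlnorm(n)
    expect_equal(wilcoxon_branch(x, y)$p, oracle_wilcoxon_p(x, y),
                 info = paste("seed", seed))
  }
})

test_that("interval dominance follows the inclusive-intersection truth table", {
  point <- function(v) list(lo = v, hi = v)
  # disjoint, medium wholly above the plasma censoring interval
  r <- sign_branch(list(lo = 0, hi = 6.4), point(10))
  expect_equal(c(r$n_plus, r$n_minus, r$n_tie), c(0L, 1L, 0L))
  # overlapping unbounded tails are a tie
  r <- sign_branch(list(lo = 20000, hi = Inf), list(lo = 10000, hi = Inf))
  expect_equal(r$n_tie, 1L)
  # touching endpoints count as intersecting
  r <- sign_branch(list(lo = 5, hi = 10), list(lo = 10, hi = 12))
  expect_equal(r$n_tie, 1L)
  # nested intervals intersect
  r <- sign_branch(list(lo = 1, hi = 10), list(lo = 3, hi = 4))
  expect_equal(r$n_tie, 1L)
  # plasma wholly above
  r <- sign_branch(point(100), list(lo = 0, hi = 3.2))
  expect_equal(c(r$n_plus, r$n_minus), c(1L, 0L))
})

test_that("the sign test is exact binomial, two-sided, with ties excluded", {
  mk <- function(n_plus, n_minus, n_tie = 0) {
    lo_p <- c(rep(10, n_plus), rep(1, n_minus), rep(5, n_tie))
    hi_p <- lo_p
    lo_m <- c(rep(1, n_plus), rep(10, n_minus), rep(5, n_tie))
    hi_m <- lo_m
    sign_branch(list(lo = lo_p, hi = hi_p), list(lo = lo_m, hi = hi_m))
  }
  r <- mk(10, 0)
  expect_equal(r$p, 2 / 2^10)
  expect_equal(r$p, oracle_sign_p(10, 0))
  expect_equal(r$direction, "plasma")
  r <- mk(1, 9)
  expect_equal(r$p, oracle_sign_p(9, 1))
  expect_equal(r$p, 0.021484375)
  expect_equal(r$direction, "medium")
  for (np in 0:6) for (nm in 0:6)
    expect_equal(mk(np, nm, 2)$p, oracle_sign_p(np, nm),
                 info = sprintf("n_plus=%d n_minus=%d", np, nm))
  r <- mk(0, 0, 5)
  expect_equal(r$p, 1)
  expect_equal(r$direction, "none")
})

test_that("the sign branch is invariant to monotone rescaling of each pair", {
  set.seed(77)
  n <- 15
  lo_p <- runif(n, 0, 5); hi_p <- lo_p + rbinom(n, 1, 0.5) * runif(n, 0, 5)
  lo_m <- runif(n, 0, 5); hi_m <- lo_m + rbinom(n, 1, 0.5) * runif(n, 0, 5)
  base <- sign_branch(list(lo = lo_p, hi = hi_p), list(lo = lo_m, hi = hi_m))
  s <- runif(n, 0.1, 10)  # per-pair positive scale applied to both members
  scaled <- sign_branch(list(lo = lo_p * s, hi = hi_p * s),
                        list(lo = lo_m * s, hi = hi_m * s))
  expect_equal(scaled, base)
  cubed <- sign_branch(list(lo = lo_p^3, hi = hi_p^3),
                       list(lo = lo_m^3, hi = hi_m^3))
  expect_equal(cubed, base)
})

test_that("Benjamini-Hochberg adjustment is step-up, monotone, and capped", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification matches direction and significance, with reference rows appended", {
  res <- data.frame(analyte = c("A", "B", "C"),
                    branch = c("quantitative", "qualitative", "qualitative"),
                    criterion = c("Wilcoxon", "Sign", "Sign"),
                    direction = c("plasma", "medium", "medium"),
                    statistic = c(5, NA, NA),
                    n_plus = c(NA, 1L, 3L), n_minus = c(NA, 11L, 4L),
                    n_tie = c(NA, 2L, 7L),
                    p_raw = c(0.002, 0.01, 0.6),
                    stringsAsFactors = FALSE)
  res$p_adj <- bh_adjust(res$p_raw)
  tab <- classify_analytes(res, references = c("R1", "R2"), alpha = 0.05)
  expect_s3_class(tab, "xplex_comparison")
  expect_equal(nrow(tab), 5L)
  cls <- stats::setNames(tab$class, tab$analyte)
  expect_equal(unname(cls[c("A", "B", "C")]),
               c("elevated_in_plasma", "elevated_in_medium", "not_differential"))
  expect_true(all(cls[c("R1", "R2")] == "not_differential"))
  expect_equal(unname(attr(tab, "counts")),
               c(1L, 1L, 3L))
  expect_equal(tab$elevated_in_medium[tab$analyte == "B"], "Yes")
  # no signal: everything not differential
  res2 <- res; res2$p_raw <- res2$p_adj <- rep(1, 3)
  tab2 <- classify_analytes(res2, alpha = 0.05)
  expect_true(all(tab2$class == "not_differential"))
  res3 <- res; res3$p_adj[2] <- NA
  expect_error(classify_analytes(res3), "B")
})

test_that("compare_study routes branches by the 40% rule and tests accordingly", {
  sim <- generate_study(study_preset(seed = 1))
  tab <- compare_study(sim$study, references = c("TNF-a", "IP-10"))
  expect_equal(nrow(tab), 41L)
  ms <- summarize_missingness(sim$study)
  branch <- route_branches(ms)
  for (a in setdiff(sim$study$plasma$analytes, c("TNF-a", "IP-10"))) {
    expect_equal(tab$branch[tab$analyte == a], unname(branch[a]), info = a)
  }
  expect_true(all(tab$criterion[tab$branch == "qualitative"] == "Sign"))
  quali <- tab[tab$branch == "qualitative" & !tab$reference, ]
  expect_true(all(quali$n_plus + quali$n_minus + quali$n_tie == 23L))
})
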