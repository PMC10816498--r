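ct_table <- function(ct_ref, ct_targets, gene = "MCP1", sample = "S1",
                     population = "plaque_bulk") {
  rbind(
    data.frame(sample = sample, population = population, gene = "UBC",
               ct = ct_ref, stringsAsFactors = FALSE),
    data.frame(sample = sample, population = population, gene = gene,
               ct = ct_targets, stringsAsFactors = FALSE))
}

test_that("delta-Ct relative expression follows the doubling identities", {
  rel <- relative_expression(ct_table(20, 20))
  expect_equal(rel$rel, 1)
  rel <- relative_expression(ct_table(20, 21))
  expect_equal(rel$rel, 0.5)
  rel <- relative_expression(ct_table(20, 17))
  expect_equal(rel$rel, 8)
})

test_that("undetected targets receive the floor and a detect = FALSE flag", {
  m <- rbind(ct_table(20, NA), ct_table(22, 25, sample = "S2"))
  rel <- relative_expression(m, floor = 1e-4)
  expect_equal(rel$rel[rel$sample == "S1"], 1e-4)
  expect_false(rel$detect[rel$sample == "S1"])
  expect_true(rel$detect[rel$sample == "S2"])
  # floor must sit at least two-fold below the smallest detected value
  expect_warning(relative_expression(m, floor = 0.2), "two-fold")
  expect_error(relative_expression(ct_table(NA, 25)), "reference")
  expect_error(relative_expression(ct_table(20, 50)), "45")
})

test_that("relative expression is invariant to a constant Ct offset per sample", {
  m1 <- rbind(ct_table(20, 24), ct_table(18, 26, sample = "S2"))
  m2 <- m1; m2$ct <- m2$ct + c(3, 3, -2, -2)  # per-sample constant shifts
  expect_equal(relative_expression(m1)$rel, relative_expression(m2)$rel)
})

test_that("tissue comparison pairs samples and detects a planted Ct shift", {
  mk_pair <- function(seed, shift) {
    set.seed(seed)
    samples <- paste0("S", 1:9)
    ref_p <- rnorm(9, 20, 0.3); ref_b <- rnorm(9, 20, 0.3)
    tgt_p <- ref_p + rnorm(9, 2, 0.5) + shift
    tgt_b <- ref_b + rnorm(9, 2, 0.5)
    rbind(
      data.frame(sample = samples, population = "plaque_bulk", gene = "UBC",
                 ct = ref_p, stringsAsFactors = FALSE),
      data.frame(sample = samples, population = "plaque_bulk", gene = "MCP1",
                 ct = tgt_p, stringsAsFactors = FALSE),
      data.frame(sample = samples, population = "blood_bulk", gene = "UBC",
                 ct = ref_b, stringsAsFactors = FALSE),
      data.frame(sample = samples, population = "blood_bulk", gene = "MCP1",
                 ct = tgt_b, stringsAsFactors = FALSE))
  }
  # identical groups: p = 1
  m <- mk_pair(1, 0)
  m$ct[m$population == "blood_bulk"] <- m$ct[m$population == "plaque_bulk"]
  rel <- relative_expression(m)
  r <- compare_tissues(rel, "MCP1", c("plaque_bulk", "blood_bulk"))
  expect_equal(r$p, 1)
  # a -3 cycle shift in plaque (8-fold up) across 9 pairs is significant
  hits <- 0L
  for (seed in 1:10) {
    rel <- relative_expression(mk_pair(seed, -3))
    r <- compare_tissues(rel, "MCP1", c("plaque_bulk", "blood_bulk"))
    hits <- hits + (r$p < 0.05 && r$direction == "plaque_bulk")
  }
  expect_equal(hits, 10L)
  # unpaired samples are excluded with a warning
  m2 <- mk_pair(2, -3)
  m2 <- m2[!(m2$sample == "S9" & m2$population == "blood_bulk"), ]
  rel2 <- relative_expression(m2)
  expect_warning(r2 <- compare_tissues(rel2, "MCP1", c("plaque_bulk", "blood_bulk")),
                 "S9")
  expect_equal(r2$n, 8L)
})

test_that("calibrating to a population puts that population at 1 per sample", {
  m <- rbind(ct_table(20, 24, population = "plaque_macro"),
             ct_table(20, 26, population = "plaque_T"))
  rel <- relative_expression(m)
  cal <- calibrate_expression(rel, "plaque_macro")
  expect_equal(cal$rel[cal$population == "plaque_macro"], 1)
  # two extra cycles in T cells: four-fold lower than the calibrator
  expect_equal(cal$rel[cal$population == "plaque_T"], 0.25)
  expect_error(calibrate_expression(rel, "blood_T"), "calibrator")
})

test_that("heatmap grids preserve undetected flags and round-trip through CSV", {
  samples <- paste0("S", 1:10)
  m <- do.call(rbind, lapply(samples, function(s) rbind(
    data.frame(sample = s, population = "plaque_T", gene = "UBC", ct = 20,
               stringsAsFactors = FALSE),
    data.frame(sample = s, population = "plaque_T", gene = "MCP1",
               ct = if (match(s, samples) <= 8) NA else 24,
               stringsAsFactors = FALSE),
    data.frame(sample = s, population = "plaque_macro", gene = "UBC", ct = 20,
               stringsAsFactors = FALSE),
    data.frame(sample = s, population = "plaque_macro", gene = "MCP1", ct = 23,
               stringsAsFactors = FALSE))))
  rel <- relative_expression(m)
  grid <- expression_heatmap_table(rel, "MCP1")
  expect_equal(sum(!grid$detect["plaque_T", ]), 8L)
  expect_equal(sum(!grid$detect["plaque_macro", ]), 0L)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_table(grid, tf)
  back <- read_heatmap_table(tf)
  expect_equal(back$rel, grid$rel)
  expect_equal(back$detect, grid$detect)
})
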