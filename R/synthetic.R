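#' Specification of one synthetic analyte
#'
#' Concentrations are log-normal: the latent log2 concentration of analyte
#' `a` in sample `s` is
#' `baseline_log2 + sample_scale[s] + effect_log2 * [specimen == medium] + N(0, residual_sd)`,
#' where `sample_scale` is a sample-level factor shared by all analytes of
#' that sample (the structure under which geometric-mean reference
#' normalization is exactly the right correction). Values outside
#' `[llod, ulod]` are censored as in a real bead-immunoassay run.
#'
#' @param name analyte name.
#' @param baseline_log2 log2 pg/mL latent mean in plasma.
#' @param residual_sd per-cell biological/technical noise, log2 units (>= 0).
#' @param effect_log2 planted medium-vs-plasma shift in log2 units
#'   (positive = higher in conditioned medium).
#' @param stable designated-stable flag: a reference-like analyte (zero
#'   effect, low residual noise, detection limits that never censor it).
#' @param llod,ulod detection limits in pg/mL (0 < llod < ulod).
#' @return A one-row data.frame.
#' @export
analyte_spec <- function(name, baseline_log2, residual_sd, effect_log2 = 0,
                         stable = FALSE, llod = 1, ulod = 10000) {
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  if (!(llod > 0 && llod < ulod)) stop("need 0 < llod < ulod for ", name)
  data.frame(name = name, baseline_log2 = baseline_log2,
             residual_sd = residual_sd, effect_log2 = effect_log2,
             stable = stable, llod = llod, ulod = ulod,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic paired-study generator
#'
#' @param analytes data.frame of stacked [analyte_spec] rows.
#' @param n_pairs number of patients (paired plasma/medium samples);
#'   default 23, the size of the study the generator emulates.
#' @param seed integer seed; generation is bitwise reproducible given
#'   (config, seed).
#' @param sample_scale_sd sd (log2 units) of the per-sample scale factor
#'   (default 0.5, i.e. about 1.4-fold typical sample-to-sample swing).
#' @param p_extrapolate probability that a sub-LLOD cell is emitted as an
#'   extrapolated value carrying its latent concentration rather than as a
#'   bare below-range flag (default 0.3).
#' @return A list of class `xplex_synth_config`.
#' @export
synthetic_config <- function(analytes, n_pairs = 23L, seed = 1L,
                             sample_scale_sd = 0.5, p_extrapolate = 0.3) {
  if (anyDuplicated(analytes$name)) stop("duplicate analyte names")
  if (n_pairs < 2) stop("need at least 2 pairs")
  if (sample_scale_sd < 0 || p_extrapolate < 0 || p_extrapolate > 1)
    stop("invalid sample_scale_sd or p_extrapolate")
  structure(list(analytes = analytes, n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed), sample_scale_sd = sample_scale_sd,
                 p_extrapolate = p_extrapolate),
            class = "xplex_synth_config")
}

censor_panel <- function(latent_log2, spec, p_extrapolate) {
  # latent_log2: patients x analytes; returns conc/status matrices
  conc <- 2^latent_log2
  status <- matrix("measured", nrow(conc), ncol(conc))
  for (j in seq_len(ncol(conc))) {
    below <- conc[, j] < spec$llod[j]
    above <- conc[, j] > spec$ulod[j]
    if (any(below)) {
      extr <- below & stats::runif(nrow(conc)) < p_extrapolate
      status[below & !extr, j] <- "below_range"
      status[extr, j] <- "extrapolated"
      conc[below & !extr, j] <- NA_real_
    }
    if (any(above)) {
      status[above, j] <- "above_range"
      conc[above, j] <- NA_real_
    }
  }
  list(conc = conc, status = status)
}

#' Generate a paired synthetic study with known ground truth
#'
#' @param config an [synthetic_config] object.
#' @return List with `study` (an [paired_study]) and `truth` (class
#'   `xplex_synth_truth`): the config echo, the latent log2 concentration
#'   arrays, per-analyte realized censoring fractions, the designated
#'   stable set, and the expected differential class per analyte.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "xplex_synth_config"))
  spec <- config$analytes
  n <- config$n_pairs
  m <- nrow(spec)
  patients <- sprintf("P%02d", seq_len(n))
  set.seed(config$seed)
  scale_p <- stats::rnorm(n, 0, config$sample_scale_sd)
  scale_m <- stats::rnorm(n, 0, config$sample_scale_sd)
  noise <- function() matrix(stats::rnorm(n * m), n, m) *
    matrix(spec$residual_sd, n, m, byrow = TRUE)
  base <- matrix(spec$baseline_log2, n, m, byrow = TRUE)
  eff <- matrix(spec$effect_log2, n, m, byrow = TRUE)
  lat_p <- base + scale_p + noise()
  lat_m <- base + eff + scale_m + noise()
  dimnames(lat_p) <- dimnames(lat_m) <- list(patients, spec$name)
  cp <- censor_panel(lat_p, spec, config$p_extrapolate)
  cm <- censor_panel(lat_m, spec, config$p_extrapolate)
  plasma <- xplex_panel("plasma", cp$conc, cp$status, patients, spec$name,
                        dilution_factor = 2)
  medium <- xplex_panel("medium", cm$conc, cm$status, patients, spec$name,
                        dilution_factor = 1)
  limits <- xplex_limits(spec$name, spec$llod, spec$ulod)
  study <- paired_study(plasma, medium, limits)
  cens_frac <- function(st) colMeans(st != "measured")
  expected <- ifelse(spec$effect_log2 > 0, "elevated_in_medium",
                     ifelse(spec$effect_log2 < 0, "elevated_in_plasma",
                            "not_differential"))
  truth <- structure(list(config = config,
                          latent_plasma = lat_p, latent_medium = lat_m,
                          sample_scale_plasma = stats::setNames(scale_p, patients),
                          sample_scale_medium = stats::setNames(scale_m, patients),
                          censored_fraction_plasma = cens_frac(cp$status),
                          censored_fraction_medium = cens_frac(cm$status),
                          stable_analytes = spec$name[spec$stable],
                          expected_class = stats::setNames(expected, spec$name)),
                     class = "xplex_synth_truth")
  list(study = study, truth = truth)
}

#' Preset emulating the 41-plex carotid-plaque study design
#'
#' A 23-pair, 41-analyte configuration mirroring the structure of the
#' motivating dataset: exactly five analytes (PDGF-AA, MIP-1beta, MDC,
#' IP-10, TNF-alpha) detectable in every sample by construction, of which
#' TNF-alpha and IP-10 are the designated stable pair (zero effect, low
#' noise); six analytes planted higher in plasma and twenty-two higher in
#' conditioned medium; most remaining analytes heavily censored in plasma
#' and less so in medium, so roughly nine non-reference analytes are routed
#' to the quantitative branch.
#'
#' @param seed integer seed stored in the config.
#' @return An [synthetic_config] object.
#' @export
study_preset <- function(seed = 1L) {
  sp <- function(...) analyte_spec(...)
  rows <- list(
    # complete-by-construction candidate references (llod far below, ulod far above)
    sp("TNF-a",      6.0, 0.15, 0,    TRUE,  llod = 0.01, ulod = 1e6),
    sp("IP-10",      6.5, 0.15, 0,    TRUE,  llod = 0.01, ulod = 1e6),
    sp("MDC",        7.0, 0.50, -2,   FALSE, llod = 0.01, ulod = 1e6),
    sp("PDGF-AA",    7.5, 0.50, -2,   FALSE, llod = 0.01, ulod = 1e6),
    sp("MIP-1b",     6.0, 0.50, +2,   FALSE, llod = 0.01, ulod = 1e6),
    # well-detected non-reference analytes (quantitative branch)
    sp("Eotaxin",    3.0, 1.0, -2,    FALSE, llod = 2^0.5, ulod = 2^13),
    sp("RANTES",     3.0, 1.0, -2,    FALSE, llod = 2^0.5, ulod = 2^13),
    sp("sCD40L",    11.5, 1.0, -2,    FALSE, llod = 2^0.5, ulod = 2^13),
    sp("PDGF-AB/BB", 3.0, 1.0, -2,    FALSE, llod = 2^0.5, ulod = 2^13),
    sp("IL-15",      1.5, 1.0, +2,    FALSE, llod = 2^0.5, ulod = 2^13),
    sp("IL-5",       2.0, 1.0, 0,     FALSE, llod = 2^0.5, ulod = 2^13)
  )
  medium_up <- c("IL-1b", "IL-1RA", "IL-2", "IL-4", "IL-6", "IL-7", "IL-8",
                 "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IFN-a2", "MCP-1",
                 "MCP-3", "MIP-1a", "GRO-a", "VEGF", "G-CSF", "GM-CSF", "TGF-a")
  for (nm in medium_up)
    rows[[length(rows) + 1L]] <- sp(nm, -2.0, 1.0, +5, FALSE,
                                    llod = 2, ulod = 2^13)
  nulls <- c("IL-1a", "IL-3", "IL-9", "IL-17A", "IFN-g", "TNF-b",
             "Fractalkine", "EGF", "FGF-2", "Flt-3L")
  for (nm in nulls)
    rows[[length(rows) + 1L]] <- sp(nm, -1.0, 1.0, 0, FALSE,
                                    llod = 2, ulod = 2^13)
  synthetic_config(do.call(rbind, rows), n_pairs = 23L, seed = seed)
}

#' Write a generated study to disk in the package's CSV dialects
#'
#' @param sim output of [generate_study].
#' @param dir output directory (created if needed).
#' @param dialect panel dialect for [write_panel].
#' @return `dir`, invisibly. Writes `plasma.csv`, `medium.csv`,
#'   `limits.csv`, and `truth.json` (config echo and designated stable set).
#' @export
write_study <- function(sim, dir, dialect = "wide") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(sim$study$plasma, file.path(dir, "plasma.csv"), dialect)
  write_panel(sim$study$medium, file.path(dir, "medium.csv"), dialect)
  write_limits(sim$study$limits, file.path(dir, "limits.csv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(seed = truth$config$seed, n_pairs = truth$config$n_pairs,
         sample_scale_sd = truth$config$sample_scale_sd,
         p_extrapolate = truth$config$p_extrapolate,
         stable_analytes = truth$stable_analytes,
         expected_class = as.list(truth$expected_class),
         analytes = truth$config$analytes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
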