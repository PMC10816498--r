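#' Legal per-cell value statuses
#'
#' A measured cell carries a concentration inside the detection range, an
#' extrapolated cell carries a concentration below the lower limit of detection
#' that the instrument software extrapolated from the standard curve, and
#' below-/above-range cells carry no concentration at all (they are the
#' "initially missing" values of a bead-immunoassay run).
#'
#' @export
xplex_statuses <- c("measured", "extrapolated", "below_range", "above_range")

#' Construct an annotated concentration panel for one specimen type
#'
#' The central data container of the package: a patients x analytes grid of
#' concentrations (pg/mL) with a per-cell status flag recording how each value
#' relates to the assay's detection range.
#'
#' @param specimen_type `"plasma"` or `"medium"`.
#' @param conc numeric patients x analytes matrix; `NA` for cells whose status
#'   is `below_range` or `above_range`.
#' @param status character matrix of the same dimension with entries from
#'   [xplex_statuses].
#' @param patients,analytes optional character vectors overriding the
#'   dimnames of `conc`; both must be unique.
#' @param dilution_factor specimen dilution applied before the assay
#'   (>= 1). Plasma diluted 1:1 with assay buffer has factor 2; neat
#'   conditioned medium has factor 1. Defaults follow the specimen type.
#'
#' @return An object of class `xplex_panel`: a list with elements
#'   `specimen_type`, `patients`, `analytes`, `conc`, `status`,
#'   `dilution_factor`.
#' @export
xplex_panel <- function(specimen_type, conc, status,
                        patients = rownames(conc), analytes = colnames(conc),
                        dilution_factor = if (identical(specimen_type, "plasma")) 2 else 1) {
  specimen_type <- match.arg(specimen_type, c("plasma", "medium"))
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  status <- as.matrix(status)
  if (!identical(dim(conc), dim(status)))
    stop("concentration and status grids must have identical dimensions")
  if (is.null(patients)) patients <- paste0("P", seq_len(nrow(conc)))
  if (is.null(analytes)) analytes <- paste0("A", seq_len(ncol(conc)))
  patients <- as.character(patients); analytes <- as.character(analytes)
  if (length(patients) != nrow(conc) || length(analytes) != ncol(conc))
    stop("patient/analyte name lengths do not match the grid")
  if (anyDuplicated(patients))
    stop("duplicate patient id: ", paste(unique(patients[duplicated(patients)]), collapse = ", "))
  if (anyDuplicated(analytes))
    stop("duplicate analyte name: ", paste(unique(analytes[duplicated(analytes)]), collapse = ", "))
  bad <- !(status %in% xplex_statuses)
  if (any(bad))
    stop("unknown status token(s): ", paste(unique(status[bad]), collapse = ", "))
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1 || dilution_factor < 1)
    stop("dilution_factor must be a single number >= 1")
  oor <- status %in% c("below_range", "above_range")
  if (any(oor & !is.na(conc)))
    stop("below_range/above_range cells must carry no concentration")
  if (any(!oor & is.na(conc)))
    stop("measured/extrapolated cells must carry a concentration (absent cells are illegal)")
  if (any(conc < 0, na.rm = TRUE))
    stop("negative concentration encountered")
  dimnames(conc) <- dimnames(status) <- list(patients, analytes)
  structure(list(specimen_type = specimen_type, patients = patients,
                 analytes = analytes, conc = conc, status = status,
                 dilution_factor = dilution_factor),
            class = "xplex_panel")
}

#' @export
print.xplex_panel <- function(x, ...) {
  cat(sprintf("<xplex_panel: %s, %d patients x %d analytes, dilution %g>\n",
              x$specimen_type, length(x$patients), length(x$analytes),
              x$dilution_factor))
  tab <- table(factor(x$status, levels = xplex_statuses))
  cat("  cell statuses:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a per-analyte detection-limits table
#'
#' @param analyte character vector of analyte names.
#' @param llod lower limit of detection in pg/mL: the concentration of the
#'   maximally diluted assay standard divided by 2 is conventionally used as
#'   a substitution value, but `llod` itself is the lowest standard.
#' @param ulod upper limit of detection in pg/mL (least diluted standard).
#'
#' @return A `data.frame` of class `xplex_limits` with columns
#'   `analyte`, `llod`, `ulod`.
#' @export
xplex_limits <- function(analyte, llod, ulod) {
  analyte <- as.character(analyte)
  llod <- as.numeric(llod); ulod <- as.numeric(ulod)
  if (anyDuplicated(analyte))
    stop("duplicate analyte in limits: ",
         paste(unique(analyte[duplicated(analyte)]), collapse = ", "))
  bad <- !(is.finite(llod) & is.finite(ulod) & llod > 0 & llod < ulod)
  if (any(bad))
    stop("detection limits must satisfy 0 < llod < ulod; offending analyte(s): ",
         paste(analyte[bad], collapse = ", "))
  structure(data.frame(analyte = analyte, llod = llod, ulod = ulod,
                       stringsAsFactors = FALSE),
            class = c("xplex_limits", "data.frame"))
}

limits_for <- function(limits, analytes) {
  i <- match(analytes, limits$analyte)
  if (anyNA(i))
    stop("limits table lacks analyte(s): ", paste(analytes[is.na(i)], collapse = ", "))
  limits[i, , drop = FALSE]
}

#' Bundle paired plasma and conditioned-medium panels with detection limits
#'
#' Both panels must cover the same patients (the paired design) and the same
#' analytes, and the limits table must cover every analyte.
#'
#' @param plasma,medium [xplex_panel] objects with matching `specimen_type`.
#' @param limits an [xplex_limits] table covering every analyte.
#' @return An object of class `xplex_study`.
#' @export
paired_study <- function(plasma, medium, limits) {
  stopifnot(inherits(plasma, "xplex_panel"), inherits(medium, "xplex_panel"),
            inherits(limits, "xplex_limits"))
  if (plasma$specimen_type != "plasma" || medium$specimen_type != "medium")
    stop("panels must be passed as plasma = <plasma panel>, medium = <medium panel>")
  if (!identical(plasma$patients, medium$patients))
    stop("paired design requires identical patient ids in both panels")
  if (!identical(plasma$analytes, medium$analytes))
    stop("both panels must measure the same analytes in the same order")
  limits_for(limits, plasma$analytes)  # coverage check
  structure(list(plasma = plasma, medium = medium, limits = limits),
            class = "xplex_study")
}

#' @export
print.xplex_study <- function(x, ...) {
  cat(sprintf("<xplex_study: %d paired samples, %d analytes>\n",
              length(x$plasma$patients), length(x$plasma$analytes)))
  print(x$plasma); print(x$medium)
  invisible(x)
}

#' Check concentration/status consistency against the detection limits
#'
#' Verifies the per-cell contract: a measured concentration lies within
#' `[llod, ulod]` and an extrapolated one lies below `llod`. Real instrument
#' exports occasionally break these by rounding, so violations are reported
#' rather than thrown.
#'
#' @param study an [paired_study] object.
#' @return A data.frame of violations (zero rows when clean) with columns
#'   `specimen`, `patient`, `analyte`, `status`, `concentration`, `problem`.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "xplex_study"))
  out <- list()
  for (p in list(study$plasma, study$medium)) {
    lim <- limits_for(study$limits, p$analytes)
    ll <- matrix(lim$llod, nrow(p$conc), ncol(p$conc), byrow = TRUE)
    uu <- matrix(lim$ulod, nrow(p$conc), ncol(p$conc), byrow = TRUE)
    bad_meas <- p$status == "measured" & (p$conc < ll | p$conc > uu)
    bad_extr <- p$status == "extrapolated" & p$conc >= ll
    for (nm in c("bad_meas", "bad_extr")) {
      w <- which(get(nm), arr.ind = TRUE)
      if (nrow(w)) out[[length(out) + 1L]] <- data.frame(
        specimen = p$specimen_type,
        patient = p$patients[w[, 1]],
        analyte = p$analytes[w[, 2]],
        status = p$status[w],
        concentration = p$conc[w],
        problem = if (nm == "bad_meas") "measured value outside [llod, ulod]"
                  else "extrapolated value not below llod",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(specimen = character(), patient = character(),
                      analyte = character(), status = character(),
                      concentration = numeric(), problem = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
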