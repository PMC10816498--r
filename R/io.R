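#' Read an annotated concentration panel from disk
#'
#' Two tabular dialects are accepted. The *wide* dialect has one row per
#' patient (first column = patient id) and one column per analyte; each cell
#' is either a plain number (a measured concentration in pg/mL), the token
#' `<LLOD` (below the detection range), `>ULOD` (above it), or `<LLOD:v`
#' (a value `v` extrapolated below the lowest standard). The *long* dialect
#' has columns `patient`, `analyte`, `concentration`, `status` with status
#' drawn from [xplex_statuses]. `.xlsx` files are read through the readxl
#' package when it is installed; anything else is parsed as delimited text.
#'
#' @param path file to read (CSV/TSV, or XLSX with readxl available).
#' @param specimen_type `"plasma"` or `"medium"`.
#' @param dialect `"wide"` (default) or `"long"`.
#' @param dilution_factor see [xplex_panel]; defaults by specimen type.
#' @return A validated [xplex_panel].
#' @export
read_panel <- function(path, specimen_type, dialect = c("wide", "long"),
                       dilution_factor = if (identical(specimen_type, "plasma")) 2 else 1) {
  dialect <- match.arg(dialect)
  df <- read_table_any(path)
  if (dialect == "wide") parse_wide_panel(df, specimen_type, dilution_factor, path)
  else parse_long_panel(df, specimen_type, dilution_factor, path)
}

read_table_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading ", path, " requires the readxl package")
    return(as.data.frame(readxl::read_excel(path, col_types = "text"),
                         stringsAsFactors = FALSE))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

parse_cell <- function(s) {
  # -> list(conc = numeric NA-able, status = character), or NULL if unparseable
  s <- trimws(s)
  if (identical(s, "<LLOD")) return(list(conc = NA_real_, status = "below_range"))
  if (identical(s, ">ULOD")) return(list(conc = NA_real_, status = "above_range"))
  if (startsWith(s, "<LLOD:")) {
    v <- suppressWarnings(as.numeric(substring(s, 7L)))
    if (is.na(v)) return(NULL)
    return(list(conc = v, status = "extrapolated"))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) return(NULL)
  list(conc = v, status = "measured")
}

format_cell <- function(conc, status) {
  switch(status,
         measured = format(conc, digits = 15, scientific = FALSE, trim = TRUE),
         extrapolated = paste0("<LLOD:", format(conc, digits = 15,
                                                scientific = FALSE, trim = TRUE)),
         below_range = "<LLOD",
         above_range = ">ULOD",
         stop("unknown status: ", status))
}

parse_wide_panel <- function(df, specimen_type, dilution_factor, path) {
  if (ncol(df) < 2) stop("wide panel needs a patient column plus analyte columns: ", path)
  patients <- as.character(df[[1]])
  analytes <- colnames(df)[-1]
  n <- length(patients); m <- length(analytes)
  conc <- matrix(NA_real_, n, m)
  status <- matrix(NA_character_, n, m)
  bad <- character()
  for (j in seq_len(m)) {
    col <- as.character(df[[j + 1L]])
    for (i in seq_len(n)) {
      cell <- parse_cell(col[i])
      if (is.null(cell)) {
        bad <- c(bad, sprintf("row %d (patient %s), column %s: '%s'",
                              i, patients[i], analytes[j], col[i]))
      } else {
        conc[i, j] <- cell$conc
        status[i, j] <- cell$status
      }
    }
  }
  if (length(bad))
    stop("unparseable cell(s) in ", path, ":\n  ", paste(bad, collapse = "\n  "))
  xplex_panel(specimen_type, conc, status, patients, analytes, dilution_factor)
}

parse_long_panel <- function(df, specimen_type, dilution_factor, path) {
  need <- c("patient", "analyte", "concentration", "status")
  if (!all(need %in% colnames(df)))
    stop("long panel must have columns ", paste(need, collapse = ", "), ": ", path)
  patients <- unique(as.character(df$patient))
  analytes <- unique(as.character(df$analyte))
  key <- paste(df$patient, df$analyte, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate patient x analyte row(s) in ", path, ": ",
         paste(unique(sub("\r", " / ", key[duplicated(key)])), collapse = ", "))
  conc <- matrix(NA_real_, length(patients), length(analytes),
                 dimnames = list(patients, analytes))
  status <- matrix(NA_character_, length(patients), length(analytes),
                   dimnames = list(patients, analytes))
  full <- as.vector(outer(patients, analytes, paste, sep = "\r"))
  missing_cells <- setdiff(full, key)
  if (length(missing_cells))
    stop("absent patient x analyte cell(s) are illegal in ", path, ": ",
         paste(sub("\r", " / ", utils::head(missing_cells, 10L)), collapse = ", "))
  st <- as.character(df$status)
  unknown <- setdiff(unique(st), xplex_statuses)
  if (length(unknown))
    stop("unknown status token(s) in ", path, ": ", paste(unknown, collapse = ", "))
  cv <- suppressWarnings(as.numeric(as.character(df$concentration)))
  i <- match(as.character(df$patient), patients)
  j <- match(as.character(df$analyte), analytes)
  conc[cbind(i, j)] <- cv
  status[cbind(i, j)] <- st
  conc[status %in% c("below_range", "above_range")] <- NA_real_
  xplex_panel(specimen_type, conc, status, patients, analytes, dilution_factor)
}

#' Write a panel back to disk
#'
#' Inverse of [read_panel]: `read_panel(write_panel(p, f), ...)` reproduces
#' `p` exactly (values, statuses, ordering) in either dialect.
#'
#' @param panel an [xplex_panel].
#' @param path output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(panel, "xplex_panel"))
  if (dialect == "wide") {
    cells <- matrix(mapply(format_cell, panel$conc, panel$status),
                    nrow = length(panel$patients))
    df <- data.frame(patient = panel$patients, cells, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("patient", panel$analytes)
  } else {
    idx <- expand.grid(i = seq_along(panel$patients), j = seq_along(panel$analytes))
    df <- data.frame(patient = panel$patients[idx$i],
                     analyte = panel$analytes[idx$j],
                     concentration = panel$conc[cbind(idx$i, idx$j)],
                     status = panel$status[cbind(idx$i, idx$j)],
                     stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-analyte detection-limits table
#'
#' Expects one row per analyte with columns `analyte`, `llod`, `ulod`
#' (pg/mL). When `analytes` is supplied, coverage is enforced and the rows
#' are returned in that order.
#'
#' @param path CSV/TSV (or XLSX) file.
#' @param analytes optional character vector the table must cover.
#' @return An [xplex_limits] table.
#' @export
read_limits <- function(path, analytes = NULL) {
  df <- read_table_any(path)
  need <- c("analyte", "llod", "ulod")
  if (!all(need %in% colnames(df)))
    stop("limits table must have columns ", paste(need, collapse = ", "), ": ", path)
  lim <- xplex_limits(df$analyte, as.numeric(df$llod), as.numeric(df$ulod))
  if (!is.null(analytes)) lim <- xplex_limits_subset(lim, analytes)
  lim
}

xplex_limits_subset <- function(lim, analytes) {
  sub <- limits_for(lim, analytes)
  xplex_limits(sub$analyte, sub$llod, sub$ulod)
}

#' Write a detection-limits table
#' @param limits an [xplex_limits] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_limits <- function(limits, path) {
  utils::write.csv(as.data.frame(limits), path, row.names = FALSE)
  invisible(path)
}

#' Write the differential-representation table to CSV
#'
#' Columns: `analyte`, `criterion` (`Wilcoxon` or `Sign`),
#' `elevated_in_plasma`, `elevated_in_medium` (`Yes`/`No`), `p_raw`, `p_adj`.
#' The round trip through [read_comparison_table] is lossless.
#'
#' @param tab a comparison table as produced by [classify_analytes] (class
#'   `xplex_comparison`), or any data.frame with the columns above.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(tab, path) {
  cols <- c("analyte", "criterion", "elevated_in_plasma", "elevated_in_medium",
            "p_raw", "p_adj")
  df <- as.data.frame(tab)[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write comparison table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a differential-representation table written by [write_comparison_table]
#' @param path CSV path.
#' @return A data.frame with the comparison-table columns.
#' @export
read_comparison_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$p_raw <- as.numeric(df$p_raw)
  df$p_adj <- as.numeric(df$p_adj)
  df
}
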