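#' Canonical monitoring-record columns
#'
#' The long-format table has one row per site-month. \code{site_id} and
#' \code{date} are required; every measurement may be missing (\code{NA}),
#' never zero-filled. Units: water_temp degC; light_attenuation_k
#' dimensionless (literal form) or per metre (exponential form); nutrients
#' (tp, tn, dtp, dip, no3, nh4) mg/L; chl_a ug/L; ph pH units; do mg/L; cond
#' uS/cm; secchi m; the four quantum yields (fv_fm_tc, fv_fm_bc, df_fm_tc,
#' df_fm_bc) dimensionless in [0, 1]; densities (c_total, c_cyano,
#' c_microcystis) cells/L.
#'
#' @return character vector of canonical column names.
#' @export
recordColumns <- function() {
  c("site_id", "date",
    "water_temp", "light_attenuation_k",
    "tp", "tn", "dtp", "dip", "no3", "nh4",
    "chl_a", "ph", "do", "cond", "secchi",
    "fv_fm_tc", "fv_fm_bc", "df_fm_tc", "df_fm_bc",
    "c_total", "c_cyano", "c_microcystis")
}

.yieldCols   <- c("fv_fm_tc", "fv_fm_bc", "df_fm_tc", "df_fm_bc")
.densityCols <- c("c_total", "c_cyano", "c_microcystis")

.floorMonth <- function(d) as.Date(format(as.Date(d), "%Y-%m-01"))

#' Validate a monitoring-record table
#'
#' Checks the record invariants: required \code{site_id} and \code{date},
#' quantum yields in [0, 1], non-negative cell densities, and the composition
#' ordering c_microcystis <= c_cyano <= c_total wherever the pairs are
#' present. Violations raise an error naming the offending row.
#'
#' @param records data.frame of monitoring records (canonical columns).
#' @param tol numeric slack for the ordering checks.
#' @return the validated data.frame, invisibly, with \code{date} floored to
#'   month resolution.
#' @export
validateRecords <- function(records, tol = 1e-9) {
  stopifnot(is.data.frame(records))
  if (!all(c("site_id", "date") %in% names(records)))
    stop("records must carry site_id and date columns")
  unknown <- setdiff(names(records), recordColumns())
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  if (anyNA(records$site_id) || anyNA(records$date))
    stop("site_id and date may not be missing")
  records$date <- .floorMonth(records$date)
  for (col in intersect(.yieldCols, names(records))) {
    bad <- which(!is.na(records[[col]]) &
                   (records[[col]] < -tol | records[[col]] > 1 + tol))
    if (length(bad))
      stop(sprintf("%s outside [0, 1] in row(s) %s", col,
                   paste(utils::head(bad, 5L), collapse = ", ")))
  }
  for (col in intersect(.densityCols, names(records))) {
    bad <- which(!is.na(records[[col]]) & records[[col]] < -tol)
    if (length(bad))
      stop(sprintf("negative density %s in row(s) %s", col,
                   paste(utils::head(bad, 5L), collapse = ", ")))
  }
  chk <- function(lo, hi) {
    if (all(c(lo, hi) %in% names(records))) {
      bad <- which(!is.na(records[[lo]]) & !is.na(records[[hi]]) &
                     records[[lo]] > records[[hi]] * (1 + tol) + tol)
      if (length(bad))
        stop(sprintf("%s exceeds %s in row(s) %s", lo, hi,
                     paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  chk("c_microcystis", "c_cyano")
  chk("c_cyano", "c_total")
  invisible(records)
}

#' Read monitoring records from a long-format CSV
#'
#' One row per site-month, header required. Column names are mapped to the
#' canonical set (see [recordColumns()]) either directly or through
#' \code{dialect}, a named character vector \code{c(file_name = "canonical_name")}
#' absorbing naming variants. Columns that match nothing raise an error
#' listing the unmatched names. Empty cells become \code{NA}, never zero.
#'
#' @param path CSV file path.
#' @param dialect optional named character vector mapping file column names
#'   to canonical names.
#' @return validated data.frame of monitoring records, \code{date} as
#'   \code{Date} at month resolution.
#' @seealso [writeRecords()], [validateRecords()]
#' @export
readRecords <- function(path, dialect = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!is.null(dialect)) {
    hit <- names(df) %in% names(dialect)
    names(df)[hit] <- unname(dialect[names(df)[hit]])
  }
  unknown <- setdiff(names(df), recordColumns())
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "),
         " (map them with the dialect argument)")
  df$site_id <- as.character(df$site_id)
  df$date <- .floorMonth(df$date)
  num <- setdiff(names(df), c("site_id", "date"))
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  validateRecords(df)
  df
}

#' Write monitoring records to CSV
#'
#' Numeric values are serialised at full double precision (17 significant
#' digits) so that a write/read round trip is lossless; missing values are
#' written as empty cells.
#'
#' @param records data.frame of monitoring records.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRecords <- function(records, path) {
  validateRecords(records)
  out <- records
  out$date <- format(.floorMonth(out$date), "%Y-%m-%d")
  for (col in setdiff(names(out), c("site_id", "date"))) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Cross-site monthly means
#'
#' Collapses a multi-site record table to one record per month by averaging
#' every numeric field across sites, ignoring missing values (a month-field
#' with no observations stays \code{NA}). This is the series the
#' report-table-style seasonal fits use, so that a 24-month campaign yields
#' n = 24 and an overall F on (3, 20) df. Idempotent: applying it to its own
#' output returns the same table.
#'
#' @param records data.frame of monitoring records.
#' @return data.frame with one row per month, \code{site_id = "pooled"}.
#' @export
monthlySiteMean <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no records supplied")
  validateRecords(records)
  records$date <- .floorMonth(records$date)
  months <- sort(unique(records$date))
  num <- setdiff(names(records), c("site_id", "date"))
  out <- data.frame(site_id = rep("pooled", length(months)), date = months,
                    stringsAsFactors = FALSE)
  for (col in num) {
    out[[col]] <- vapply(months, function(m) {
      v <- records[[col]][records$date == m]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  out
}
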