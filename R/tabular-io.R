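# Measurement CSV ingestion and JSON report serialization.

ELASTICITY_COLUMNS <- c("animal_id", "day", "part", "replicate",
                        "emean_kpa", "sd_kpa")

#' Read elastography measurements from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header containing at least
#' `animal_id, day, part, replicate, emean_kpa, sd_kpa`; extra columns
#' (e.g. Emin/Emax exported by the device) are parsed but ignored. Part
#' names are normalized to lower case. Row order is irrelevant.
#'
#' @param path path to the CSV file.
#' @return a data.frame of elasticity records, one per CSV data row.
#' @export
read_elasticity_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("measurement file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(ELASTICITY_COLUMNS, names(df))
  if (length(missing_cols))
    stop_validation(sprintf("measurement CSV is missing required column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  parse_num <- function(col, kind) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
    na_rows <- which(is.na(v))
    if (length(na_rows))
      stop_validation(sprintf("non-numeric %s '%s' at data row %d of '%s'",
                              kind, df[[col]][na_rows[1]], na_rows[1], path))
    v
  }
  out <- data.frame(
    animal_id = as.character(df$animal_id),
    day = as.integer(parse_num("day", "day")),
    part = tolower(trimws(df$part)),
    replicate = as.integer(parse_num("replicate", "replicate")),
    emean_kpa = parse_num("emean_kpa", "emean_kpa"),
    sd_kpa = parse_num("sd_kpa", "sd_kpa"),
    stringsAsFactors = FALSE
  )
  bad_part <- which(!out$part %in% PARTS)
  if (length(bad_part))
    stop_validation(sprintf("unknown part '%s' at data row %d (expected head/body/tail)",
                            out$part[bad_part[1]], bad_part[1]))
  bad_day <- which(out$day < min(STUDY_DAYS) | out$day > max(STUDY_DAYS))
  if (length(bad_day))
    stop_validation(sprintf("day %d at data row %d outside the 1..14 study window",
                            out$day[bad_day[1]], bad_day[1]))
  bad_e <- which(out$emean_kpa < YM_SCALE_KPA[1] | out$emean_kpa > YM_SCALE_KPA[2])
  if (length(bad_e))
    stop_validation(sprintf("emean_kpa %.3f at data row %d outside the device scale [0, 80]",
                            out$emean_kpa[bad_e[1]], bad_e[1]))
  if (any(out$sd_kpa < 0))
    stop_validation("sd_kpa must be non-negative")
  if (any(out$replicate < 1))
    stop_validation("replicate must be >= 1")
  out
}

# ---- JSON reports ----------------------------------------------------

report_body <- function(report) {
  if (inherits(report, "composition_fractions")) {
    return(list(type = "composition_fractions",
                Rr = round(100 * report[["Rr"]], 2),
                Rp = round(100 * report[["Rp"]], 2),
                Rb = round(100 * report[["Rb"]], 2),
                units = "percent"))
  }
  if (inherits(report, "transition_report")) {
    return(list(type = "transition_report",
                changepoint_days = report$changepoint_days,
                segment_slopes = report$segment_slopes,
                sse = report$sse))
  }
  if (inherits(report, "reversal_report")) {
    return(list(type = "reversal_report",
                reversal_day = if (is.na(report$reversal_day)) NULL
                               else report$reversal_day))
  }
  if (inherits(report, "heterogeneity_report")) {
    return(list(type = "heterogeneity_report",
                within_sd = report$within_sd,
                between_sd = report$between_sd))
  }
  if (is.list(report)) return(report)
  stop_validation("unsupported report type")
}

#' Write a result record as a JSON report
#'
#' Key order is stable; composition fractions are serialized as
#' percentages rounded to 2 decimals (the precision of the study tables).
#' Every report carries package-version provenance.
#'
#' @param report a `composition_fractions`, `transition_report`,
#'   `reversal_report`, `heterogeneity_report`, or a plain named list.
#' @param path destination file.
#' @param config optional resolved configuration echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = NULL) {
  if (!dir.exists(dirname(path)))
    stop_io(sprintf("directory '%s' does not exist", dirname(path)))
  body <- report_body(report)
  body$provenance <- list(
    tool = "qpia",
    version = as.character(utils::packageVersion("qpia"))
  )
  if (!is.null(config)) body$provenance$config <- config
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path path written by [write_report()].
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("report '%s' does not exist", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
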