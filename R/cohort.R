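#' Cohort of incident breast-cancer cases
#'
#' A cohort is a data frame with one row per patient and the columns
#' \describe{
#'   \item{patient_id}{unique identifier}
#'   \item{mode}{`"screen"` or `"symptomatic"` mode of primary detection}
#'   \item{diameter_mm}{primary tumour diameter at diagnosis, mm (must
#'     exceed the minimum screen-detectable diameter for screen-detected
#'     cases)}
#'   \item{screen_lags_years}{times of prior negative screens before
#'     diagnosis, years, as a semicolon-separated string (empty allowed; the
#'     detection screen of a screen-detected case is not listed)}
#'   \item{treat_start_years}{years from diagnosis to treatment start}
#'   \item{treat_stop_years}{years from diagnosis to treatment stop (equal
#'     to `treat_start_years` for never-treated patients)}
#'   \item{followup_years}{follow-up from diagnosis, years (the event or
#'     censoring time)}
#'   \item{event}{`"mets"` (distant metastasis detected),
#'     `"censored"`, or `"mets_at_dx"` (metastasis already present at
#'     primary diagnosis; requires `followup_years == 0`)}
#' }
#'
#' @param df A data frame with the columns above.
#' @param const Size constants used for validation.
#' @return `as_cohort()`: the validated data frame with class `nm_cohort`.
#'   `validate_cohort()`: invisibly `TRUE`, or an error listing offending
#'   rows.
#' @examples
#' df <- data.frame(patient_id = 1, mode = "symptomatic", diameter_mm = 18,
#'                  screen_lags_years = "1;3", treat_start_years = 0.25,
#'                  treat_stop_years = 5.25, followup_years = 8,
#'                  event = "censored")
#' as_cohort(df)
#' @export
as_cohort <- function(df, const = size_constants()) {
  validate_cohort(df, const)
  df$patient_id <- as.character(df$patient_id)
  df$screen_lags_years <- as.character(df$screen_lags_years)
  class(df) <- unique(c("nm_cohort", class(df)))
  df
}

cohort_columns <- c("patient_id", "mode", "diameter_mm", "screen_lags_years",
                    "treat_start_years", "treat_stop_years", "followup_years",
                    "event")

#' @rdname as_cohort
#' @export
validate_cohort <- function(df, const = size_constants()) {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  probs <- character(0)
  note <- function(rows, msg) {
    if (length(rows))
      probs <<- c(probs, sprintf("row %d: %s", rows, msg))
  }
  note(which(!df$mode %in% c("screen", "symptomatic")),
       "mode must be 'screen' or 'symptomatic'")
  note(which(!df$event %in% c("mets", "censored", "mets_at_dx")),
       "event must be 'mets', 'censored' or 'mets_at_dx'")
  note(which(!is.finite(df$diameter_mm) | df$diameter_mm <= const$d_cell),
       "diameter_mm must exceed the single-cell diameter")
  note(which(df$mode == "screen" & df$diameter_mm <= const$d0),
       "screen-detected diameter must exceed the minimum detectable diameter")
  note(which(!is.finite(df$treat_start_years) | df$treat_start_years < 0),
       "treat_start_years must be non-negative")
  note(which(!is.finite(df$treat_stop_years) |
               df$treat_stop_years < df$treat_start_years),
       "treat_stop_years must be >= treat_start_years")
  note(which(!is.finite(df$followup_years) | df$followup_years < 0),
       "followup_years must be non-negative")
  note(which(df$event == "mets_at_dx" & df$followup_years > 0),
       "mets_at_dx implies followup_years == 0")
  lags <- parse_screen_lags(df$screen_lags_years)
  bad_lag <- vapply(lags, function(l) anyNA(l) || any(l <= 0) ||
                      anyDuplicated(l) > 0, logical(1))
  note(which(bad_lag),
       "screen_lags_years must be distinct positive numbers separated by ';'")
  note(which(anyDuplicated(df$patient_id) > 0 &
               duplicated(df$patient_id)), "duplicate patient_id")
  if (length(probs))
    stop("invalid cohort:\n", paste(" ", probs, collapse = "\n"))
  invisible(TRUE)
}

parse_screen_lags <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(s) {
    if (length(s) == 0L) return(numeric(0))
    suppressWarnings(as.numeric(s))   # tolerates surrounding whitespace
  })
}

format_screen_lags <- function(lags) {
  vapply(lags, function(l) paste(format(l, trim = TRUE, digits = 10),
                                 collapse = ";"), character(1))
}

#' Read or write a cohort CSV
#'
#' Plain-CSV serialisation of the cohort schema documented in [as_cohort()].
#' Reading validates every row and reports schema violations with row
#' numbers; writing is lossless for the schema columns (latent simulator
#' columns such as the true growth rate are dropped).
#'
#' @param path File path.
#' @param cohort A cohort (`nm_cohort` or compatible data frame).
#' @return `read_cohort()`: an `nm_cohort`. `write_cohort()`: `path`,
#'   invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' cohort <- simulate_cohort(simulation_config(n_patients = 50, seed = 1))
#' write_cohort(cohort, tmp)
#' identical(nrow(read_cohort(tmp)), 50L)
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       screen_lags_years = "character"))
  as_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort)[cohort_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.nm_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d screen-detected, %d symptomatic; %d events, %d at diagnosis)\n",
              nrow(x), sum(x$mode == "screen"), sum(x$mode == "symptomatic"),
              sum(x$event == "mets"), sum(x$event == "mets_at_dx")))
  NextMethod()
}
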