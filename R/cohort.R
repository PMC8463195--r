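# Cohort container: a validated data.frame, one row per procedure.

#' Column schema of a cohort data.frame
#'
#' Feature columns describe one lesion/procedure; operator columns carry the
#' assigned operator's experience profile; outcome columns the two binary
#' endpoints. Booleans are stored as logical in R and as 0/1 in CSV.
#'
#' @return Character vector of required column names, in canonical order.
#' @export
cohort_columns <- function() {
  c("case_id", "operator_id",
    "years_performing", "annual_volume", "last_year_success_rate",
    "age_years", "prior_mi", "prior_failed_attempt",
    "prior_cabg_target_vessel", "target_vessel",
    "blunt_stump", "calcification", "calcification_severe",
    "bend_ge45", "severe_angulation", "occlusion_length_mm",
    "distal_disease", "rentrop_grade", "in_stent", "ostial",
    "technical_success", "procedural_success")
}

.bool_cols <- c("prior_mi", "prior_failed_attempt", "prior_cabg_target_vessel",
                "blunt_stump", "calcification", "calcification_severe",
                "bend_ge45", "severe_angulation", "distal_disease",
                "in_stent", "ostial", "technical_success",
                "procedural_success")

.vessels <- c("LAD", "LCX", "RCA", "LM")

#' Construct a validated cohort
#'
#' Checks the schema and every row-level invariant of the case-record model:
#' severe calcification implies calcification, severe angulation implies a
#' bend >= 45 degrees, Rentrop grade in 0..3, occlusion length >= 0, age >=
#' 18, success rate in [0, 1], unique case ids, and procedural success
#' implying technical success (the procedural endpoint nests the technical
#' one). Violations are reported with the offending row numbers.
#'
#' @param x data.frame with the columns of [cohort_columns()].
#' @param provenance optional character string recording how the cohort was
#'   produced (seed, configuration hash).
#' @return `x` with class `cto_cohort` prepended.
#' @export
as_cohort <- function(x, provenance = NULL) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in .bool_cols) {
    v <- x[[col]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) {
        bad <- which(!(v %in% c(0, 1)))
        stop(sprintf("column '%s' must be 0/1; violated at row(s) %s",
                     col, .row_str(bad)))
      }
      x[[col]] <- v == 1
    } else if (!is.logical(v)) {
      stop(sprintf("column '%s' must be logical or 0/1", col))
    }
    if (anyNA(x[[col]])) {
      stop(sprintf("column '%s' has missing values at row(s) %s; missing",
                   col, .row_str(which(is.na(x[[col]])))),
           " values are rejected, not imputed")
    }
  }
  x$target_vessel <- as.character(x$target_vessel)
  .check_rows(x$target_vessel %in% .vessels,
              "target_vessel must be one of LAD/LCX/RCA/LM")
  .check_rows(x$rentrop_grade %in% 0:3, "rentrop_grade must be in {0,1,2,3}")
  .check_rows(x$occlusion_length_mm >= 0, "occlusion_length_mm must be >= 0")
  .check_rows(x$age_years >= 18, "age_years must be >= 18")
  .check_rows(x$last_year_success_rate >= 0 & x$last_year_success_rate <= 1,
              "last_year_success_rate must be in [0,1]")
  .check_rows(x$years_performing >= 0, "years_performing must be >= 0")
  .check_rows(x$annual_volume >= 0, "annual_volume must be >= 0")
  .check_rows(!(x$calcification_severe & !x$calcification),
              "calcification_severe requires calcification")
  .check_rows(!(x$severe_angulation & !x$bend_ge45),
              "severe_angulation requires bend_ge45")
  .check_rows(!(x$procedural_success & !x$technical_success),
              "endpoint ordering violated: procedural_success without technical_success")
  if (anyDuplicated(x$case_id)) {
    stop("case_id values must be unique; duplicated: ",
         paste(unique(x$case_id[duplicated(x$case_id)]), collapse = ", "))
  }
  class(x) <- c("cto_cohort", "data.frame")
  attr(x, "provenance") <- provenance
  x
}

.row_str <- function(idx, max_show = 5L) {
  shown <- paste(utils::head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ...")
  shown
}

.check_rows <- function(ok, msg) {
  if (!all(ok)) {
    stop(sprintf("%s; violated at row(s) %s", msg, .row_str(which(!ok))))
  }
  invisible(TRUE)
}

#' @export
print.cto_cohort <- function(x, ...) {
  cat(sprintf("CTO-PCI cohort: %d procedures, %d operators\n",
              nrow(x), length(unique(x$operator_id))))
  if (nrow(x) > 0) {
    cat(sprintf("  technical success: %d (%s%%), procedural success: %d (%s%%)\n",
                sum(x$technical_success),
                percent(sum(x$technical_success), nrow(x)),
                sum(x$procedural_success),
                percent(sum(x$procedural_success), nrow(x))))
  }
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  provenance:", prov, "\n")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' The file must carry a header row with the [cohort_columns()] schema;
#' booleans are 0/1. Every row-level invariant is enforced on read and
#' violations name the offending rows.
#'
#' @param path path to a UTF-8 CSV file.
#' @return A validated `cto_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_cohort(df, provenance = paste0("read from ", path))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans are written as 0/1 so the file
#' round-trips through the schema unchanged.
#'
#' @param cohort a `cto_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cto_cohort"))
  out <- as.data.frame(cohort)[, cohort_columns()]
  for (col in .bool_cols) out[[col]] <- as.integer(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
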