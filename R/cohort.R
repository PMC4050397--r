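#' Claims cohort of CABG hospitalization episodes
#'
#' A cohort is a data frame with one row per CABG admission, holding the
#' aggregated medical-use fields available in claims data, the coded-diagnosis
#' sets, and the surveillance SSI label used as the reference standard.
#' Treatment items are episode totals without time stamps, so no field carries
#' date information.
#'
#' Required columns:
#' \describe{
#'   \item{patient_id}{opaque character identifier, unique within the cohort}
#'   \item{age}{age in years, integer >= 0}
#'   \item{sex}{"male" or "female"}
#'   \item{los}{length of stay in days, > 0}
#'   \item{vessels_obstructed}{number of obstructed vessels, integer >= 1}
#'   \item{antibiotic_types}{count of distinct antibiotic substances, >= 0}
#'   \item{antibiotic_ddd_total}{total antibiotic dose in defined daily doses
#'     (DDD), >= 0}
#'   \item{cefazolin_ddd}{cefazolin dose in DDD, >= 0 and never above the
#'     total}
#'   \item{atc_codes_used}{list-column of ATC code sets (character vectors)}
#'   \item{index_secondary_dx}{list-column: ICD-9-CM secondary diagnoses of the
#'     index hospitalization}
#'   \item{postdischarge_dx}{list-column: ICD-9-CM primary or secondary
#'     diagnoses on readmissions/ambulatory visits within one year of
#'     discharge}
#'   \item{ssi_label}{surveillance-confirmed SSI status, 0/1}
#' }
#'
#' @param x a data frame with the columns above; the three code columns may be
#'   semicolon-separated character vectors, which are split into list-columns.
#' @return `as_cohort()` returns the validated data frame with class
#'   `ssi_cohort`.
#' @examples
#' df <- data.frame(
#'   patient_id = "p1", age = 65, sex = "male", los = 12,
#'   vessels_obstructed = 2, antibiotic_types = 1,
#'   antibiotic_ddd_total = 4, cefazolin_ddd = 4,
#'   atc_codes_used = "J01DB04", index_secondary_dx = "",
#'   postdischarge_dx = "", ssi_label = 0
#' )
#' cohort <- as_cohort(df)
#' @export
as_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c(
    "patient_id", "age", "sex", "los", "vessels_obstructed",
    "antibiotic_types", "antibiotic_ddd_total", "cefazolin_ddd",
    "atc_codes_used", "index_secondary_dx", "postdischarge_dx", "ssi_label"
  )
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("cohort is missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("atc_codes_used", "index_secondary_dx", "postdischarge_dx")) {
    x[[col]] <- if (is.list(x[[col]])) {
      lapply(x[[col]], as.character)  # plain list column, drops any AsIs
    } else {
      split_codes(x[[col]])
    }
  }
  x$patient_id <- as.character(x$patient_id)
  x$ssi_label <- as.integer(x$ssi_label)
  validate_cohort(x)
  class(x) <- c("ssi_cohort", "data.frame")
  x
}

#' @keywords internal
#' @noRd
validate_cohort <- function(x, cefazolin_code = cefazolin_atc()) {
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("%s (first offending row: %d, patient_id %s)",
                   msg, i[1], x$patient_id[i[1]]), call. = FALSE)
    }
  }
  bad(duplicated(x$patient_id), "duplicate patient_id")
  bad(!x$sex %in% c("male", "female"), "sex must be 'male' or 'female'")
  bad(is.na(x$age) | x$age < 0, "age must be >= 0")
  bad(is.na(x$los) | x$los <= 0, "los must be > 0")
  bad(is.na(x$vessels_obstructed) | x$vessels_obstructed < 1,
      "vessels_obstructed must be >= 1")
  bad(is.na(x$antibiotic_types) | x$antibiotic_types < 0,
      "antibiotic_types must be >= 0")
  bad(is.na(x$antibiotic_ddd_total) | x$antibiotic_ddd_total < 0,
      "antibiotic_ddd_total must be >= 0")
  bad(is.na(x$cefazolin_ddd) | x$cefazolin_ddd < 0, "cefazolin_ddd must be >= 0")
  bad(x$cefazolin_ddd > x$antibiotic_ddd_total + 1e-9,
      "cefazolin_ddd exceeds antibiotic_ddd_total")
  bad(x$antibiotic_types == 0 & x$antibiotic_ddd_total > 0,
      "antibiotic_ddd_total > 0 requires antibiotic_types >= 1")
  has_code <- vapply(x$atc_codes_used, function(s) cefazolin_code %in% s, logical(1))
  bad(x$cefazolin_ddd > 0 & !has_code,
      "cefazolin_ddd > 0 requires the cefazolin ATC code in atc_codes_used")
  bad(x$cefazolin_ddd == 0 & has_code,
      "cefazolin ATC code present but cefazolin_ddd is 0")
  bad(!x$ssi_label %in% c(0L, 1L), "ssi_label must be 0 or 1")
  invisible(x)
}

#' Read and write cohort CSV files
#'
#' The on-disk form is UTF-8 CSV with a header row; the set-valued columns
#' (`atc_codes_used`, `index_secondary_dx`, `postdischarge_dx`) are
#' semicolon-separated within their cell.
#'
#' @param path path to a CSV file.
#' @param cohort an `ssi_cohort` (or coercible data frame).
#' @return `read_cohort()` returns an `ssi_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"),
                        fileEncoding = "UTF-8")
  as_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  flat <- as.data.frame(cohort)
  for (col in c("atc_codes_used", "index_secondary_dx", "postdischarge_dx")) {
    flat[[col]] <- join_codes(flat[[col]])
  }
  for (col in c("los", "antibiotic_ddd_total", "cefazolin_ddd")) {
    # 17 significant digits so doubles survive the text round-trip exactly
    flat[[col]] <- formatC(flat[[col]], digits = 17, format = "g")
  }
  utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' @export
print.ssi_cohort <- function(x, ...) {
  cat(sprintf("<ssi_cohort> %d episodes, %d surveillance SSI (%.2f%%)\n",
              nrow(x), sum(x$ssi_label), 100 * mean(x$ssi_label)))
  utils::str(as.data.frame(utils::head(x, 3)), give.attr = FALSE)
  invisible(x)
}
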