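#' ICD-9-CM code sets for SSI case finding
#'
#' Two code lists drive the ICD-9-CM-based model: codes looked up among the
#' secondary diagnoses of the index CABG hospitalization, and codes looked up
#' among the primary or secondary diagnoses of readmissions and ambulatory
#' visits within one year of discharge. Restricting the index admission to
#' secondary positions avoids counting infections that predate the surgery.
#' The septicemia range 038.0-038.4 is expanded to its five constituent codes.
#'
#' @return a list with character vectors `index_codes` and
#'   `postdischarge_codes` (dotted canonical form). Every index code also
#'   appears in the post-discharge list.
#' @export
icd9_code_sets <- function() {
  index <- c("996.03", "996.61", "996.72", "998.5")
  post <- c(
    "038.0", "038.1", "038.2", "038.3", "038.4", "038.8", "038.9",
    "682.6", "682.9", "780.6", "790.7", "875.0", "875.1",
    "891.0", "891.1", "996.03", "996.61", "996.72", "998.3", "998.5"
  )
  list(index_codes = index, postdischarge_codes = post)
}

#' Normalize ICD-9-CM code strings
#'
#' Canonical form is dotted ("998.5"). Undotted 5-digit forms get the dot
#' inserted after the third digit ("99850" -> "998.50"); undotted 4-digit
#' forms are ambiguous (the decimal point could fall after the second or
#' third digit) and are rejected; bare 3-digit category codes pass through.
#'
#' @param codes character vector of ICD-9-CM diagnosis codes.
#' @return the normalized codes.
#' @export
normalize_icd9 <- function(codes) {
  codes <- trimws(as.character(codes))
  out <- character(length(codes))
  for (i in seq_along(codes)) {
    s <- codes[i]
    if (grepl("^[0-9]{3}\\.[0-9]{1,2}$", s) || grepl("^[0-9]{3}$", s)) {
      out[i] <- s
    } else if (grepl("^[0-9]{5}$", s)) {
      out[i] <- paste0(substr(s, 1, 3), ".", substr(s, 4, 5))
    } else if (grepl("^[0-9]{4}$", s)) {
      stop(sprintf("ambiguous undotted 4-digit ICD-9-CM code: '%s'", s))
    } else {
      stop(sprintf("malformed ICD-9-CM code: '%s'", s))
    }
  }
  out
}

#' Classify episodes with the ICD-9-CM-based model
#'
#' An episode is flagged as an SSI case when any index-hospitalization
#' secondary diagnosis matches the index code list, or any post-discharge
#' diagnosis (primary or secondary, pooled) matches the post-discharge code
#' list. Matching is exact on the normalized code string.
#'
#' @param cohort an `ssi_cohort` or coercible data frame.
#' @param codes code sets, see [icd9_code_sets()].
#' @return a `classifier_result` data frame: `patient_id`, `model_name`
#'   ("icd9"), binary `prediction`, `score` (`NA`; the model is not
#'   probabilistic).
#' @export
classify_icd9 <- function(cohort, codes = icd9_code_sets()) {
  cohort <- as_cohort(cohort)
  hit <- function(dx, set) {
    vapply(dx, function(s) length(s) > 0 && any(normalize_icd9(s) %in% set),
           logical(1))
  }
  pred <- hit(cohort$index_secondary_dx, codes$index_codes) |
    hit(cohort$postdischarge_dx, codes$postdischarge_codes)
  classifier_result(cohort$patient_id, as.integer(pred), model_name = "icd9")
}

#' @keywords internal
#' @noRd
classifier_result <- function(patient_id, prediction, score = NA_real_,
                              model_name) {
  out <- data.frame(patient_id = as.character(patient_id),
                    model_name = model_name,
                    prediction = as.integer(prediction),
                    score = as.numeric(score),
                    stringsAsFactors = FALSE)
  class(out) <- c("classifier_result", "data.frame")
  out
}
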