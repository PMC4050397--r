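#' The second-line antibiotic catalog
#'
#' The catalog of broad-spectrum/reserve antibiotic substances whose
#' administration during a CABG hospitalization flags possible treatment (as
#' opposed to routine cefazolin prophylaxis). It maps substance name to WHO
#' ATC code. Ticarcillin with enzyme inhibitor shares one ATC code (J01CR03)
#' with its plain combination row, so the catalog holds 18 unique codes.
#'
#' @return a named character vector, names = substance, values = ATC code.
#' @examples
#' catalog <- second_line_catalog()
#' is_second_line("J01XA01", catalog)  # vancomycin -> TRUE
#' @export
second_line_catalog <- function() {
  c(
    "Ceftazidime"                        = "J01DD02",
    "Aztreonam"                          = "J01DF01",
    "Piperacillin"                       = "J01CA12",
    "Piperacillin and enzyme inhibitor"  = "J01CR05",
    "Tazobactam"                         = "J01CG02",
    "Ticarcillin"                        = "J01CA13",
    "Ticarcillin and enzyme inhibitor"   = "J01CR03",
    "Amoxicillin and enzyme inhibitor"   = "J01CR02",
    "Cefepime"                           = "J01DE01",
    "Cefpirome"                          = "J01DE02",
    "Imipenem and enzyme inhibitor"      = "J01DH51",
    "Meropenem"                          = "J01DH02",
    "Doripenem"                          = "J01DH04",
    "Colistin"                           = "J01XB01",
    "Tigecycline"                        = "J01AA12",
    "Vancomycin"                         = "J01XA01",
    "Teicoplanin"                        = "J01XA02",
    "Daptomycin"                         = "J01XX09"
  )
}

#' Canonical cefazolin ATC code
#'
#' Cefazolin is the standard first-line prophylactic agent for CABG; its WHO
#' ATC code is J01DB04. The code is a package option so cohorts coded under a
#' different convention can be accommodated.
#'
#' @return the cefazolin ATC code string.
#' @export
cefazolin_atc <- function() {
  getOption("ssiclaims.cefazolin_atc", "J01DB04")
}

#' Test whether an ATC code is a second-line antibiotic
#'
#' @param atc_code a character vector of ATC codes.
#' @param catalog catalog as returned by [second_line_catalog()].
#' @return logical vector; `TRUE` iff the code is in the catalog (exact string
#'   match). Unknown codes simply give `FALSE`.
#' @export
is_second_line <- function(atc_code, catalog = second_line_catalog()) {
  stopifnot(is.character(atc_code), all(nzchar(atc_code)))
  atc_code %in% catalog
}

#' Surrogate-criteria thresholds
#'
#' The six claims-derived surrogate criteria are binary indicators cut from
#' episode-level utilisation: more than `types_gt` distinct antibiotics, more
#' than `ddd_gt` DDD of antibiotics in total, more than `cefazolin_ddd_gt` DDD
#' of cefazolin, any second-line antibiotic, length of stay above `los_gt`
#' days, and more than `vessels_gt` vessels obstructed (a proxy for operation
#' duration). All comparisons are strictly "greater than": boundary equality
#' does not satisfy a criterion.
#'
#' @param types_gt antibiotic-type threshold (default 3).
#' @param ddd_gt total antibiotic dose threshold in DDD (default 7).
#' @param cefazolin_ddd_gt cefazolin dose threshold in DDD (default 7).
#' @param los_gt length-of-stay threshold in days (default 21).
#' @param vessels_gt obstructed-vessel threshold (default 2).
#' @return a list of class `criteria_thresholds`.
#' @export
criteria_thresholds <- function(types_gt = 3, ddd_gt = 7, cefazolin_ddd_gt = 7,
                                los_gt = 21, vessels_gt = 2) {
  th <- list(types_gt = types_gt, ddd_gt = ddd_gt,
             cefazolin_ddd_gt = cefazolin_ddd_gt,
             los_gt = los_gt, vessels_gt = vessels_gt)
  if (any(vapply(th, function(v) !is.numeric(v) || length(v) != 1 || v <= 0,
                 logical(1)))) {
    stop("all criteria thresholds must be positive scalars")
  }
  structure(th, class = "criteria_thresholds")
}

#' Compute the six surrogate criteria for every episode
#'
#' @param cohort an `ssi_cohort` or coercible data frame.
#' @param thresholds a [criteria_thresholds()] object.
#' @param catalog second-line catalog, see [second_line_catalog()].
#' @return a data frame with class `criteria_matrix`: `patient_id`, the six
#'   logical flags `c1_types`, `c2_ddd`, `c3_cefazolin`, `c4_second_line`,
#'   `c5_los`, `c6_vessels`, and `n_satisfied` (0-6, the count of true
#'   flags).
#' @examples
#' cohort <- as_cohort(data.frame(
#'   patient_id = "p1", age = 70, sex = "female", los = 47.5,
#'   vessels_obstructed = 2, antibiotic_types = 6,
#'   antibiotic_ddd_total = 30, cefazolin_ddd = 0,
#'   atc_codes_used = "J01XA01", index_secondary_dx = "",
#'   postdischarge_dx = "", ssi_label = 1
#' ))
#' compute_criteria(cohort)  # c1, c2, c4, c5 true -> n_satisfied 4
#' @export
compute_criteria <- function(cohort, thresholds = criteria_thresholds(),
                             catalog = second_line_catalog()) {
  cohort <- as_cohort(cohort)
  stopifnot(inherits(thresholds, "criteria_thresholds"))
  out <- data.frame(
    patient_id = cohort$patient_id,
    c1_types = cohort$antibiotic_types > thresholds$types_gt,
    c2_ddd = cohort$antibiotic_ddd_total > thresholds$ddd_gt,
    c3_cefazolin = cohort$cefazolin_ddd > thresholds$cefazolin_ddd_gt,
    c4_second_line = vapply(cohort$atc_codes_used,
                            function(s) length(s) > 0 && any(is_second_line(s, catalog)),
                            logical(1)),
    c5_los = cohort$los > thresholds$los_gt,
    c6_vessels = cohort$vessels_obstructed > thresholds$vessels_gt,
    stringsAsFactors = FALSE
  )
  out$n_satisfied <- rowSums(out[paste0("c", 1:6, c("_types", "_ddd", "_cefazolin",
                                                    "_second_line", "_los", "_vessels"))])
  class(out) <- c("criteria_matrix", "data.frame")
  out
}
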