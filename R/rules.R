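#' Criteria-counting classification algorithms
#'
#' The three rule models turn the six binary surrogate criteria into an SSI
#' call by counting how many are satisfied:
#' \describe{
#'   \item{strict (model 1)}{positive only when all six criteria hold;}
#'   \item{moderate (model 2)}{positive when at least `k` criteria hold
#'     (default `k = 3`);}
#'   \item{loose (model 3)}{positive when any criterion holds.}
#' }
#' The three are nested: every strict positive is a moderate positive, and
#' every moderate positive is a loose positive, so sensitivity rises and
#' specificity falls from strict to loose on any data set.
#'
#' The source wording for the moderate rule ("more than three criteria") is
#' read as "at least three": the literal reading (four or more) would sit
#' close to the all-six strict rule rather than between the extremes its
#' "moderate" label implies. `k` is a parameter, so the literal reading is a
#' one-argument change.
#'
#' @param criteria a `criteria_matrix` from [compute_criteria()].
#' @param k moderate-rule count threshold, integer in 1..6.
#' @return a `classifier_result` data frame (`patient_id`, `model_name`,
#'   `prediction`, `score = NA`).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 50, seed = 1))
#' crit <- compute_criteria(cohort)
#' table(classify_loose(crit)$prediction)
#' @name rule_classifiers
NULL

#' @rdname rule_classifiers
#' @export
classify_strict <- function(criteria) {
  stopifnot(inherits(criteria, "criteria_matrix"))
  classifier_result(criteria$patient_id,
                    criteria$n_satisfied == 6L, model_name = "strict")
}

#' @rdname rule_classifiers
#' @export
classify_moderate <- function(criteria, k = 3L) {
  stopifnot(inherits(criteria, "criteria_matrix"))
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k < 1 || k > 6) {
    stop("k must be an integer between 1 and 6")
  }
  classifier_result(criteria$patient_id,
                    criteria$n_satisfied >= k, model_name = "moderate")
}

#' @rdname rule_classifiers
#' @export
classify_loose <- function(criteria) {
  stopifnot(inherits(criteria, "criteria_matrix"))
  classifier_result(criteria$patient_id,
                    criteria$n_satisfied >= 1L, model_name = "loose")
}
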