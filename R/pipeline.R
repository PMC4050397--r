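#' Configuration for a full identification experiment
#'
#' Bundles every knob of the train-on-A / verify-on-B experiment: cohort
#' sources (simulation specs or CSV paths), criteria thresholds, the
#' moderate-rule count, stepwise thresholds, tree growth and pruning
#' settings, the global seed, and which models to run. The configuration
#' round-trips losslessly through YAML.
#'
#' @param cohort_a,cohort_b a [cohort_spec()] to simulate from, or a path to
#'   a cohort CSV; `cohort_b` may be `NULL` for a training-only run.
#' @param thresholds a [criteria_thresholds()].
#' @param moderate_k moderate-rule count threshold.
#' @param stepwise_alpha entry/removal threshold for stepwise selection.
#' @param cart a [cart_params()].
#' @param cv_folds CV folds for subtree selection.
#' @param cv_rule `"min"` or `"1se"`.
#' @param prune_cart grow-only when `FALSE`.
#' @param models character vector of models to run, a subset of
#'   `c("icd9", "strict", "moderate", "loose", "logistic", "cart")`.
#' @param seed global seed for every stochastic stage.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(cohort_a = cohort_spec(center = "A"),
                              cohort_b = cohort_spec(center = "B"),
                              thresholds = criteria_thresholds(),
                              moderate_k = 3L,
                              stepwise_alpha = 0.05,
                              cart = cart_params(),
                              cv_folds = 10L,
                              cv_rule = "min",
                              prune_cart = TRUE,
                              models = c("icd9", "strict", "moderate", "loose",
                                         "logistic", "cart"),
                              seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(cohort_a = cohort_a, cohort_b = cohort_b,
                 thresholds = thresholds, moderate_k = as.integer(moderate_k),
                 stepwise_alpha = stepwise_alpha, cart = cart,
                 cv_folds = as.integer(cv_folds), cv_rule = cv_rule,
                 prune_cart = isTRUE(prune_cart),
                 models = models, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @keywords internal
#' @noRd
load_cohort_source <- function(src, seed_offset = 0L) {
  if (is.null(src)) return(NULL)
  if (inherits(src, "cohort_spec")) {
    simulate_cohort(src)
  } else if (is.character(src) && length(src) == 1) {
    read_cohort(src)
  } else if (is.data.frame(src)) {
    as_cohort(src)
  } else {
    stop("cohort source must be a cohort_spec, a CSV path or a data frame")
  }
}

#' Run the full identification experiment
#'
#' Loads or simulates the training (A) and verification (B) cohorts, fits
#' every requested model on cohort A only, scores both cohorts, and builds
#' the training/verification performance tables. Cohort B enters only at
#' scoring time, so no model ever sees its labels during fitting. Reruns with
#' an identical configuration reproduce the outputs exactly.
#'
#' When `out_dir` is given, the reports (CSV/JSON/text), the serialized
#' logistic and tree models, the simulated cohorts and a provenance record
#' (seed, package version, config) are written there.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory.
#' @return a list of class `ssi_experiment`: `report`
#'   (a `performance_report`), `rows` (per-cohort `performance_row` lists),
#'   `models` (fitted artifacts), `predictions` (per-cohort
#'   `classifier_result` list), and `cohorts`.
#' @examples
#' \donttest{
#' cfg <- experiment_config(cohort_a = cohort_spec(n = 400, seed = 7),
#'                          cohort_b = NULL, cv_folds = 5)
#' ex <- run_experiment(cfg)
#' ex$report
#' }
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cohort_a <- load_cohort_source(config$cohort_a)
  cohort_b <- load_cohort_source(config$cohort_b)
  if (length(unique(cohort_a$ssi_label)) < 2) {
    stop("training cohort has a single surveillance class; cannot fit models")
  }

  crit_a <- compute_criteria(cohort_a, config$thresholds)
  fitted <- list()
  preds_a <- list()

  if ("icd9" %in% config$models) preds_a$icd9 <- classify_icd9(cohort_a)
  if ("strict" %in% config$models) preds_a$strict <- classify_strict(crit_a)
  if ("moderate" %in% config$models) {
    preds_a$moderate <- classify_moderate(crit_a, config$moderate_k)
  }
  if ("loose" %in% config$models) preds_a$loose <- classify_loose(crit_a)
  if ("logistic" %in% config$models) {
    fitted$logistic <- train_logistic_model(
      cohort_a, alpha_enter = config$stepwise_alpha,
      alpha_remove = config$stepwise_alpha)
    preds_a$logistic <- classify_logistic(fitted$logistic, cohort_a)
  }
  if ("cart" %in% config$models) {
    fitted$cart <- train_cart_model(
      cohort_a, params = config$cart, v = config$cv_folds,
      seed = config$seed, rule = config$cv_rule, prune = config$prune_cart)
    preds_a$cart <- predict_tree(fitted$cart, cohort_a)
  }

  score_cohort <- function(cohort) {
    crit <- compute_criteria(cohort, config$thresholds)
    p <- list()
    if ("icd9" %in% config$models) p$icd9 <- classify_icd9(cohort)
    if ("strict" %in% config$models) p$strict <- classify_strict(crit)
    if ("moderate" %in% config$models) {
      p$moderate <- classify_moderate(crit, config$moderate_k)
    }
    if ("loose" %in% config$models) p$loose <- classify_loose(crit)
    if ("logistic" %in% config$models) {
      p$logistic <- classify_logistic(fitted$logistic, cohort)
    }
    if ("cart" %in% config$models) p$cart <- predict_tree(fitted$cart, cohort)
    p
  }
  preds_b <- if (!is.null(cohort_b)) score_cohort(cohort_b)

  rows_for <- function(preds, cohort) {
    lapply(preds, function(p) compute_metrics(confusion(p, cohort)))
  }
  rows <- list(training = rows_for(preds_a, cohort_a))
  if (!is.null(preds_b)) rows$verification <- rows_for(preds_b, cohort_b)
  report <- report_tables(rows$training, rows$verification)

  result <- structure(list(report = report, rows = rows, models = fitted,
                           predictions = list(training = preds_a,
                                              verification = preds_b),
                           cohorts = list(training = cohort_a,
                                          verification = cohort_b),
                           config = config),
                      class = "ssi_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, rows, file.path(out_dir, "performance"))
    if (!is.null(fitted$logistic)) {
      write_logistic_json(fitted$logistic, file.path(out_dir, "logistic_model.json"))
    }
    if (!is.null(fitted$cart)) {
      write_tree_json(fitted$cart, file.path(out_dir, "cart_model.json"))
    }
    write_cohort(cohort_a, file.path(out_dir, "cohort_A.csv"))
    if (!is.null(cohort_b)) {
      write_cohort(cohort_b, file.path(out_dir, "cohort_B.csv"))
    }
    for (p in names(result$predictions)) {
      if (!is.null(result$predictions[[p]])) {
        utils::write.csv(do.call(rbind, result$predictions[[p]]),
                         file.path(out_dir, paste0("predictions_", p, ".csv")),
                         row.names = FALSE)
      }
    }
    prov <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("ssiclaims")),
                 config = config_to_list(config))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.ssi_experiment <- function(x, ...) {
  cat("<ssi_experiment>\n")
  print(x$report)
  invisible(x)
}

#' @keywords internal plain-list form of a config (for YAML/JSON round-trips)
#' @noRd
config_to_list <- function(config) {
  src <- function(s) {
    if (inherits(s, "cohort_spec")) c(list(type = "simulate"), unclass(s))
    else if (is.character(s)) list(type = "csv", path = s)
    else NULL
  }
  list(cohort_a = src(config$cohort_a), cohort_b = src(config$cohort_b),
       thresholds = unclass(config$thresholds),
       moderate_k = config$moderate_k,
       stepwise_alpha = config$stepwise_alpha,
       cart = unclass(config$cart), cv_folds = config$cv_folds,
       cv_rule = config$cv_rule, prune_cart = config$prune_cart,
       models = config$models, seed = config$seed)
}

#' Read / write an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `write_config_yaml()` returns `path` invisibly;
#'   `read_config_yaml()` returns an `experiment_config`.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(config_to_list(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  parse_src <- function(s) {
    if (is.null(s)) return(NULL)
    if (identical(s$type, "csv")) return(s$path)
    cohort_spec(n = s$n, prevalence = s$prevalence, seed = s$seed,
                center = s$center, params = s$params, families = s$families)
  }
  experiment_config(
    cohort_a = parse_src(x$cohort_a),
    cohort_b = parse_src(x$cohort_b),
    thresholds = do.call(criteria_thresholds, x$thresholds),
    moderate_k = x$moderate_k,
    stepwise_alpha = x$stepwise_alpha,
    cart = do.call(cart_params, x$cart),
    cv_folds = x$cv_folds, cv_rule = x$cv_rule,
    prune_cart = x$prune_cart, models = unlist(x$models), seed = x$seed
  )
}
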