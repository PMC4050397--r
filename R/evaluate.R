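#' Confusion matrix of predictions against surveillance labels
#'
#' Predictions and labels are aligned by `patient_id`; any id present on one
#' side only is an error listing the offenders.
#'
#' @param predictions a `classifier_result` (columns `patient_id`,
#'   `prediction`), or a binary vector aligned with `labels`.
#' @param labels either an `ssi_cohort` (its `ssi_label` is used, matched by
#'   id) or a binary vector.
#' @return a list of class `confusion_matrix` with integer `tp`, `fp`, `fn`,
#'   `tn`.
#' @examples
#' confusion(c(1, 0, 0, 1), c(1, 0, 0, 1))  # tp 2, tn 2
#' @export
confusion <- function(predictions, labels) {
  if (is.data.frame(predictions)) {
    pred <- predictions$prediction
    pid <- predictions$patient_id
    if (is.data.frame(labels)) {
      lid <- labels$patient_id
      extra <- setdiff(pid, lid)
      miss <- setdiff(lid, pid)
      if (length(extra) || length(miss)) {
        stop("patient_id mismatch; unmatched ids: ",
             paste(utils::head(c(extra, miss), 10), collapse = ", "))
      }
      lab <- labels$ssi_label[match(pid, lid)]
    } else {
      lab <- labels
    }
  } else {
    pred <- predictions
    lab <- if (is.data.frame(labels)) labels$ssi_label else labels
  }
  if (length(pred) != length(lab)) stop("predictions and labels differ in length")
  pred <- as.integer(pred); lab <- as.integer(lab)
  if (!all(pred %in% c(0L, 1L)) || !all(lab %in% c(0L, 1L))) {
    stop("predictions and labels must be binary 0/1")
  }
  structure(list(tp = sum(pred == 1L & lab == 1L),
                 fp = sum(pred == 1L & lab == 0L),
                 fn = sum(pred == 0L & lab == 1L),
                 tn = sum(pred == 0L & lab == 0L)),
            class = "confusion_matrix")
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative integer counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' The five diagnostic accuracy metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)` and accuracy
#' `(tp+tn)/total`, each reported as numerator, denominator and percent
#' (half-up, two decimals). A zero denominator makes the metric undefined
#' (`NA`), never 0 or 100.
#'
#' @param cm a `confusion_matrix`.
#' @return a list of class `performance_row`; each metric holds
#'   `numerator`, `denominator`, `fraction`, `percent`.
#' @examples
#' m <- compute_metrics(confusion_matrix(tp = 9, fp = 37, fn = 15, tn = 956))
#' m$sensitivity$percent  # 37.5
#' m$ppv$percent          # 19.57
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("all-zero confusion matrix")
  metric <- function(num, den) {
    if (den == 0) {
      list(numerator = num, denominator = den, fraction = NA_real_,
           percent = NA_real_)
    } else {
      list(numerator = num, denominator = den, fraction = num / den,
           percent = round_half_up(100 * num / den, 2))
    }
  }
  structure(list(
    sensitivity = metric(cm$tp, cm$tp + cm$fn),
    specificity = metric(cm$tn, cm$tn + cm$fp),
    ppv = metric(cm$tp, cm$tp + cm$fp),
    npv = metric(cm$tn, cm$tn + cm$fn),
    accuracy = metric(cm$tp + cm$tn, total),
    confusion = cm
  ), class = "performance_row")
}

#' @keywords internal "PP.PP% (num/den)" cell, em dash when undefined
#' @noRd
format_metric <- function(m) {
  if (is.na(m$fraction)) return("—")
  sprintf("%.2f%% (%d/%d)", m$percent, m$numerator, m$denominator)
}

#' Performance tables in the published layout
#'
#' One row per model, cells formatted `"PP.PP% (num/den)"`, models ordered
#' ICD-9-CM first then models 1-5, for a training table (center A) and,
#' when verification results are supplied, a verification table (center B).
#'
#' @param training named list of `performance_row`s for the training cohort;
#'   names are model labels.
#' @param verification optional named list for the verification cohort.
#' @return a list of class `performance_report` with data frames `training`
#'   and (possibly `NULL`) `verification`.
#' @export
report_tables <- function(training, verification = NULL) {
  stopifnot(length(training) >= 1)
  one <- function(rows) {
    order_hint <- c("icd9", "strict", "moderate", "loose", "logistic", "cart")
    nm <- names(rows)
    nm <- c(intersect(order_hint, nm), setdiff(nm, order_hint))
    do.call(rbind, lapply(nm, function(model) {
      r <- rows[[model]]
      data.frame(model = model,
                 sensitivity = format_metric(r$sensitivity),
                 specificity = format_metric(r$specificity),
                 ppv = format_metric(r$ppv),
                 npv = format_metric(r$npv),
                 accuracy = format_metric(r$accuracy),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(training = one(training),
                 verification = if (!is.null(verification)) one(verification)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Training data\n")
  print(x$training, row.names = FALSE)
  if (!is.null(x$verification)) {
    cat("\nVerification data\n")
    print(x$verification, row.names = FALSE)
  }
  invisible(x)
}

#' Write a performance report as CSV, JSON or aligned text
#'
#' The JSON form carries the raw confusion counts alongside the percents so
#' downstream consumers never re-parse formatted cells.
#'
#' @param report a `performance_report` from [report_tables()].
#' @param rows the named `performance_row` lists the report was built from
#'   (list with elements `training` and optionally `verification`), used for
#'   the JSON counts.
#' @param path output path without extension; `.csv`, `.json` and `.txt`
#'   files are written.
#' @return the three paths, invisibly.
#' @export
write_report <- function(report, rows, path) {
  stopifnot(inherits(report, "performance_report"))
  paths <- paste0(path, c(".csv", ".json", ".txt"))
  tab <- rbind(cbind(dataset = "training", report$training),
               if (!is.null(report$verification)) {
                 cbind(dataset = "verification", report$verification)
               })
  utils::write.csv(tab, paths[1], row.names = FALSE)
  as_json_rows <- function(rr) {
    lapply(rr, function(r) {
      list(confusion = r$confusion[c("tp", "fp", "fn", "tn")],
           metrics = lapply(r[c("sensitivity", "specificity", "ppv", "npv",
                                "accuracy")],
                            function(m) m[c("numerator", "denominator",
                                            "percent")]))
    })
  }
  jsonlite::write_json(lapply(rows, as_json_rows), paths[2],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c("Training data",
           utils::capture.output(print(report$training, row.names = FALSE)))
  if (!is.null(report$verification)) {
    txt <- c(txt, "", "Verification data",
             utils::capture.output(print(report$verification, row.names = FALSE)))
  }
  writeLines(txt, paths[3])
  invisible(paths)
}

#' Published confusion counts for the two-center CABG SSI study
#'
#' The confusion counts implied by the published performance tables of the
#' two-center CABG SSI validation study (training center: 1,017 surgeries and
#' 24 SSIs; verification center: 845 and 17), one row per model and center,
#' plus the alternative logistic-model operating point reported in the
#' discussion (`model = "logistic_alt"`, training center only). These counts
#' are exact inputs: every published percent cell is reproducible from them
#' with [compute_metrics()].
#'
#' @return a data frame with columns `center`, `model`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
published_confusions <- function() {
  rows <- rbind(
    data.frame(center = "A", model = c("icd9", "strict", "moderate", "loose",
                                       "logistic", "cart", "logistic_alt"),
               tp = c(9, 1, 13, 24, 24, 21, 21),
               fp = c(37, 1, 32, 961, 54, 6, 22),
               fn = c(15, 23, 11, 0, 0, 3, 3),
               tn = c(956, 992, 961, 32, 939, 987, 971),
               stringsAsFactors = FALSE),
    data.frame(center = "B", model = c("icd9", "strict", "moderate", "loose",
                                       "logistic", "cart"),
               tp = c(6, 1, 9, 17, 16, 15),
               fp = c(25, 2, 21, 808, 42, 6),
               fn = c(11, 16, 8, 0, 1, 2),
               tn = c(803, 826, 807, 20, 786, 822),
               stringsAsFactors = FALSE)
  )
  rows
}
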