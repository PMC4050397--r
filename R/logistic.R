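#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of a binary outcome on the chosen
#' predictors, via Newton-Raphson on the log-likelihood (IRLS). Convergence is
#' declared when the largest absolute coefficient change falls below `tol`
#' (default 1e-8) or after `max_iter` iterations. The fitted probability is
#' always oriented to the positive class (`P(outcome = 1)`): a positive
#' coefficient means higher SSI risk. Reported risk-score models with the
#' opposite orientation are the mirror image (negate every coefficient, map a
#' probability cutoff c to 1 - c).
#'
#' Complete or quasi-complete separation is detected from diverging
#' coefficients or degenerate fitted probabilities; the fit is returned with
#' `separation = TRUE` and a warning rather than failing silently. A
#' rank-deficient design matrix is an error naming the collinear columns.
#'
#' @param data a data frame holding `predictors` and `outcome` columns.
#' @param predictors character vector of predictor column names (may be empty
#'   for an intercept-only model).
#' @param outcome name of the binary 0/1 outcome column (default
#'   `"ssi_label"`).
#' @param weights optional non-negative case weights (grouped data).
#' @param tol convergence tolerance on coefficient change.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `ssi_logit`: list with `coefficients` (named,
#'   intercept first), `loglik`, `deviance`, `fitted`, `iterations`,
#'   `converged`, `separation`, `predictors`, `outcome`.
#' @examples
#' d <- data.frame(x = c(rep(1, 10), rep(0, 10)),
#'                 y = c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8)))
#' coef(fit_logistic(d, "x", "y"))  # slope log(16), intercept log(1/4)
#' @export
fit_logistic <- function(data, predictors, outcome = "ssi_label",
                         weights = NULL, tol = 1e-8, max_iter = 100L) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(predictors, outcome), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot fit")
  X <- if (length(predictors)) {
    cbind(`(Intercept)` = 1, as.matrix(data[, predictors, drop = FALSE]))
  } else {
    matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  }
  storage.mode(X) <- "double"
  w0 <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  stopifnot(length(w0) == length(y), all(w0 >= 0))

  qrX <- qr(X * sqrt(w0))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is singular; collinear predictor(s): ",
         paste(dropped, collapse = ", "))
  }

  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(w0 * mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (anyNA(new_beta)) stop("IRLS produced undefined coefficients")
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  separation <- length(predictors) > 0 &&
    ((!converged && max(abs(beta)) > 10) ||
       all(pmin(mu, 1 - mu)[w0 > 0] < 1e-4))
  if (separation) {
    warning("possible complete or quasi-complete separation; ",
            "coefficient estimates are unreliable")
  }
  ll <- sum(w0 * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300))))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    loglik = ll, deviance = -2 * ll, fitted = mu,
    iterations = iter, converged = converged, separation = separation,
    predictors = predictors, outcome = outcome
  ), class = "ssi_logit")
}

#' @export
coef.ssi_logit <- function(object, ...) object$coefficients

#' @export
print.ssi_logit <- function(x, ...) {
  cat("<ssi_logit> logistic regression (IRLS),",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (x$separation) cat("  ! separation flagged\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @keywords internal predicted probabilities for new data
#' @noRd
predict_logit <- function(model, data) {
  miss <- setdiff(model$predictors, names(data))
  if (length(miss)) {
    stop("data is missing selected predictor(s): ", paste(miss, collapse = ", "))
  }
  X <- cbind(1, as.matrix(data[model$predictors], rownames.force = FALSE))
  drop(stats::plogis(X %*% model$coefficients))
}

#' Stepwise predictor selection by likelihood-ratio tests
#'
#' Classical stepwise selection on the logistic model: at each round the
#' candidate whose addition has the smallest likelihood-ratio p-value enters
#' if that p-value is below `alpha_enter`; after every entry, included
#' variables whose removal p-value exceeds `alpha_remove` are dropped
#' (worst first); rounds repeat until the model is stable. Ties are broken by
#' candidate order, so the procedure is deterministic given the data.
#'
#' @param data data frame with candidates and outcome.
#' @param candidates character vector of candidate predictor names.
#' @param outcome binary outcome column name.
#' @param alpha_enter,alpha_remove entry and removal significance thresholds
#'   (defaults 0.05 / 0.05).
#' @return character vector of selected predictor names (possibly empty), in
#'   order of entry.
#' @export
stepwise_select <- function(data, candidates, outcome = "ssi_label",
                            alpha_enter = 0.05, alpha_remove = 0.05) {
  stopifnot(length(candidates) > 0)
  selected <- character(0)
  dev_of <- function(vars) {
    fit <- suppressWarnings(fit_logistic(data, vars, outcome))
    fit$deviance
  }
  lr_p <- function(dev_small, dev_big, df = 1) {
    stats::pchisq(max(dev_small - dev_big, 0), df = df, lower.tail = FALSE)
  }
  current_dev <- dev_of(selected)
  repeat {
    changed <- FALSE
    # forward step: best admissible candidate
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- rep(NA_real_, length(pool))
      devs <- rep(NA_real_, length(pool))
      for (i in seq_along(pool)) {
        d <- tryCatch(dev_of(c(selected, pool[i])), error = function(e) NA_real_)
        devs[i] <- d
        if (!is.na(d)) pvals[i] <- lr_p(current_dev, d)
      }
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < alpha_enter) {
        best <- which(pvals == min(pvals, na.rm = TRUE))[1]  # tie: candidate order
        selected <- c(selected, pool[best])
        current_dev <- devs[best]
        changed <- TRUE
      }
    }
    # backward check: drop anything no longer significant
    repeat {
      if (!length(selected)) break
      pvals <- vapply(seq_along(selected), function(i) {
        d <- tryCatch(dev_of(selected[-i]), error = function(e) NA_real_)
        if (is.na(d)) return(0)
        lr_p(d, current_dev)
      }, numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] > alpha_remove) {
        selected <- selected[-worst]
        current_dev <- dev_of(selected)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  selected
}

#' Train the logistic identification model (model 4)
#'
#' Runs stepwise selection over the six surrogate variables in their
#' continuous form, fits the final logistic model on the training cohort, and
#' chooses the probability cutoff maximizing the Youden index on the training
#' ROC curve.
#'
#' @param cohort training `ssi_cohort`.
#' @param candidates candidate variable names (default the six surrogate
#'   variables: los, antibiotic_types, antibiotic_ddd_total, cefazolin_ddd,
#'   second_line use, vessels_obstructed).
#' @param alpha_enter,alpha_remove stepwise thresholds, see
#'   [stepwise_select()].
#' @return an object of class `ssi_logit_model`: the fitted `ssi_logit`, the
#'   selected variables, the training `ssi_roc` curve and the Youden cutoff.
#' @export
train_logistic_model <- function(cohort,
                                 candidates = c("los", "antibiotic_types",
                                                "antibiotic_ddd_total",
                                                "cefazolin_ddd", "second_line",
                                                "vessels_obstructed"),
                                 alpha_enter = 0.05, alpha_remove = 0.05) {
  d <- logistic_frame(cohort)
  selected <- stepwise_select(d, candidates, "ssi_label",
                              alpha_enter, alpha_remove)
  fit <- suppressWarnings(fit_logistic(d, selected, "ssi_label"))
  roc <- roc_and_youden(predict_logit(fit, d), d$ssi_label)
  structure(list(fit = fit, selected = selected, roc = roc,
                 cutoff = roc$youden_cutoff),
            class = "ssi_logit_model")
}

# model frame: the six surrogate variables in continuous form; the
# second-line criterion has no underlying continuum, so it enters 0/1
#' @keywords internal
#' @noRd
logistic_frame <- function(cohort) {
  cohort <- as_cohort(cohort)
  crit <- compute_criteria(cohort)
  data.frame(
    patient_id = cohort$patient_id,
    los = cohort$los,
    antibiotic_types = cohort$antibiotic_types,
    antibiotic_ddd_total = cohort$antibiotic_ddd_total,
    cefazolin_ddd = cohort$cefazolin_ddd,
    second_line = as.numeric(crit$c4_second_line),
    vessels_obstructed = cohort$vessels_obstructed,
    ssi_label = cohort$ssi_label,
    stringsAsFactors = FALSE
  )
}

#' Score a cohort with a trained logistic model
#'
#' The score is the inverse-logit of the linear predictor; the call is
#' positive when the score is at or above the cutoff ("\eqn{\ge}" at
#' equality). A cutoff of 0 therefore flags everyone.
#'
#' @param model an `ssi_logit_model` from [train_logistic_model()], or an
#'   `ssi_logit` plus explicit `cutoff`.
#' @param cohort the cohort to score.
#' @param cutoff optional probability cutoff overriding the model's.
#' @return a `classifier_result` with `score` = fitted probability.
#' @export
classify_logistic <- function(model, cohort, cutoff = NULL) {
  if (inherits(model, "ssi_logit_model")) {
    cutoff <- cutoff %||% model$cutoff
    fit <- model$fit
  } else if (inherits(model, "ssi_logit")) {
    if (is.null(cutoff)) stop("cutoff must be supplied for a bare ssi_logit")
    fit <- model
  } else stop("model must be an ssi_logit_model or ssi_logit")
  stopifnot(is.numeric(cutoff), cutoff >= 0, cutoff <= 1)
  d <- logistic_frame(cohort)
  score <- predict_logit(fit, d)
  res <- classifier_result(d$patient_id, score >= cutoff, score,
                           model_name = "logistic")
  res
}

#' Serialize / restore a logistic model as JSON
#'
#' @param model an `ssi_logit_model`.
#' @param path output file.
#' @return `write_logistic_json()` returns `path` invisibly.
#' @export
write_logistic_json <- function(model, path) {
  stopifnot(inherits(model, "ssi_logit_model"))
  obj <- list(
    selected_variables = model$selected,
    coefficients = as.list(model$fit$coefficients),
    orientation = "SSI",
    cutoff = model$cutoff,
    auc = model$roc$auc
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
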