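test_that("confusion counts perfect agreement, disagreement, and id alignment", {
  cm <- confusion(c(1, 0, 0, 1), c(1, 0, 0, 1))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  cm2 <- confusion(c(0, 1, 1, 0), c(1, 0, 0, 1))
  expect_equal(cm2$tp + cm2$tn, 0L)

  cohort <- simulate_cohort(cohort_spec(n = 60, seed = 3))
  res <- classify_icd9(cohort)
  shuffled <- res[rev(seq_len(nrow(res))), ]
  expect_identical(confusion(res, cohort), confusion(shuffled, cohort))
  res$patient_id[1] <- "ghost"
  expect_error(confusion(res, cohort), "ghost")
})

test_that("metrics reproduce the published training-table cells from counts", {
  # ICD-9-CM row of the training center
  m <- compute_metrics(confusion_matrix(tp = 9, fp = 37, fn = 15, tn = 956))
  expect_equal(m$sensitivity$percent, 37.50)
  expect_equal(m$sensitivity$numerator, 9)
  expect_equal(m$sensitivity$denominator, 24)
  expect_equal(m$specificity$percent, 96.27)
  expect_equal(m$ppv$percent, 19.57)
  expect_equal(m$npv$percent, 98.46)
  expect_equal(m$accuracy$percent, 94.89)
  expect_equal(m$accuracy$denominator, 1017)

  # decision-tree row of the training center
  m5 <- compute_metrics(confusion_matrix(tp = 21, fp = 6, fn = 3, tn = 987))
  expect_equal(m5$sensitivity$percent, 87.50)
  expect_equal(m5$specificity$percent, 99.40)
  expect_equal(m5$ppv$percent, 77.78)
  expect_equal(m5$npv$percent, 99.70)
  expect_equal(m5$accuracy$percent, 99.12)
})

test_that("perfect classifiers score 100 everywhere; zero denominators are NA", {
  m <- compute_metrics(confusion_matrix(tp = 7, fp = 0, fn = 0, tn = 93))
  for (metric in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(m[[metric]]$percent, 100)
  }
  none_flagged <- compute_metrics(confusion_matrix(tp = 0, fp = 0, fn = 5, tn = 95))
  expect_true(is.na(none_flagged$ppv$percent))   # undefined, not 0 or 100
  expect_equal(none_flagged$sensitivity$percent, 0)
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "all-zero")
})

test_that("metric identities hold exactly on every published confusion row", {
  rows <- published_confusions()
  for (i in seq_len(nrow(rows))) {
    cm <- confusion_matrix(rows$tp[i], rows$fp[i], rows$fn[i], rows$tn[i])
    m <- compute_metrics(cm)
    total <- cm$tp + cm$fp + cm$fn + cm$tn
    prev <- (cm$tp + cm$fn) / total
    # accuracy = prevalence * sensitivity + (1 - prevalence) * specificity
    expect_equal(m$accuracy$fraction,
                 prev * m$sensitivity$fraction + (1 - prev) * m$specificity$fraction)
    # Bayes inversion of PPV/NPV agrees with the direct count ratio
    if (!is.na(m$ppv$fraction)) {
      bayes_ppv <- prev * m$sensitivity$fraction /
        (prev * m$sensitivity$fraction + (1 - prev) * (1 - m$specificity$fraction))
      expect_equal(m$ppv$fraction, bayes_ppv)
    }
    if (!is.na(m$npv$fraction)) {
      bayes_npv <- (1 - prev) * m$specificity$fraction /
        ((1 - prev) * m$specificity$fraction + prev * (1 - m$sensitivity$fraction))
      expect_equal(m$npv$fraction, bayes_npv)
    }
  }
})

test_that("report cells use the percent (num/den) style and em dash for NA", {
  rows <- list(icd9 = compute_metrics(confusion_matrix(9, 37, 15, 956)),
               strict = compute_metrics(confusion_matrix(0, 0, 24, 993)))
  rep <- report_tables(rows)
  expect_equal(rep$training$sensitivity[1], "37.50% (9/24)")
  expect_equal(rep$training$ppv[1], "19.57% (9/46)")
  expect_equal(rep$training$ppv[2], "—")
  expect_null(rep$verification)

  single <- report_tables(list(cart = compute_metrics(confusion_matrix(21, 6, 3, 987))))
  expect_equal(nrow(single$training), 1)
})

test_that("reports round-trip to CSV/JSON/text with raw counts in the JSON", {
  rows <- list(
    training = list(icd9 = compute_metrics(confusion_matrix(9, 37, 15, 956))),
    verification = list(icd9 = compute_metrics(confusion_matrix(6, 25, 11, 803)))
  )
  rep <- report_tables(rows$training, rows$verification)
  base <- file.path(withr::local_tempdir(), "perf")
  write_report(rep, rows, base)
  expect_true(all(file.exists(paste0(base, c(".csv", ".json", ".txt")))))
  j <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(j$training$icd9$confusion$tp, 9)
  expect_equal(j$verification$icd9$metrics$sensitivity$percent, 35.29)
  csv <- utils::read.csv(paste0(base, ".csv"))
  expect_equal(nrow(csv), 2)
})
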