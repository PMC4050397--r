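test_that("same spec and seed reproduce the cohort exactly, including the CSV", {
  s <- cohort_spec(n = 150, seed = 2024)
  a <- simulate_cohort(s)
  b <- simulate_cohort(s)
  expect_identical(as.data.frame(a), as.data.frame(b))
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_cohort(cohort_spec(n = 150, seed = 2025)))))
})

test_that("degenerate prevalence 0 gives an all-negative cohort", {
  co <- simulate_cohort(cohort_spec(n = 80, prevalence = 0, seed = 5))
  expect_true(all(co$ssi_label == 0L))
})

test_that("every generated episode satisfies the episode invariants", {
  co <- simulate_cohort(cohort_spec(n = 3000, seed = 6))
  expect_s3_class(co, "ssi_cohort")  # as_cohort() validation already ran
  expect_true(all(co$cefazolin_ddd <= co$antibiotic_ddd_total + 1e-9))
  expect_true(all(co$antibiotic_types >= 1))
  expect_true(all(co$los > 0))
  expect_true(all(co$age >= 20 & co$age <= 100))
  expect_true(all(co$vessels_obstructed %in% 1:3))
  has_cefa <- vapply(co$atc_codes_used, function(s) cefazolin_atc() %in% s,
                     logical(1))
  expect_identical(has_cefa, co$cefazolin_ddd > 0)
})

test_that("moment_report reproduces hand-computed means on a 2-row cohort", {
  co <- make_cohort(
    make_episode(los = 10, types = 2, ddd = 6, cefazolin = 4, age = 60, ssi = 0),
    make_episode(los = 30, types = 4, ddd = 20, cefazolin = 0, atc = "J01XA01",
                 age = 70, ssi = 1)
  )
  rep <- moment_report(co)
  cell <- function(var, stat, col) {
    rep[rep$variable == var & rep$statistic == stat, col]
  }
  expect_equal(cell("los", "mean", "all"), 20)
  expect_equal(cell("los", "mean", "non_ssi"), 10)
  expect_equal(cell("los", "mean", "ssi"), 30)
  expect_equal(cell("antibiotic_ddd_total", "mean", "all"), 13)
  expect_equal(cell("cefazolin_use", "proportion", "ssi"), 0)
  expect_equal(cell("second_line_use", "proportion", "ssi"), 1)
  expect_equal(cell("n", "count", "all"), 2)
})

test_that("single-class cohorts report NA for the absent class, not an error", {
  co <- simulate_cohort(cohort_spec(n = 40, prevalence = 0, seed = 7))
  rep <- moment_report(co)
  expect_true(all(is.na(rep$ssi[rep$statistic != "count"])))
  expect_false(anyNA(rep$non_ssi[rep$statistic %in% c("mean", "proportion")]))
})

test_that("moment_report is deterministic given the cohort", {
  co <- simulate_cohort(cohort_spec(n = 200, seed = 8))
  expect_identical(moment_report(co), moment_report(co))
})

test_that("class-conditional shifts have the direction of the source cohort", {
  co <- simulate_cohort(cohort_spec(n = 20000, seed = 9))
  rep <- moment_report(co)
  cell <- function(var, stat, col) {
    rep[rep$variable == var & rep$statistic == stat, col]
  }
  expect_gt(cell("los", "mean", "ssi"), cell("los", "mean", "non_ssi"))
  expect_gt(cell("antibiotic_types", "mean", "ssi"),
            cell("antibiotic_types", "mean", "non_ssi"))
  expect_gt(cell("second_line_use", "proportion", "ssi"),
            cell("second_line_use", "proportion", "non_ssi"))
  expect_lt(cell("cefazolin_use", "proportion", "ssi"),
            cell("cefazolin_use", "proportion", "non_ssi"))
  expect_lt(cell("vessels_obstructed", "mean", "ssi"),
            cell("vessels_obstructed", "mean", "non_ssi"))
  # SSI-class LOS median sits near its 47.5-day target
  expect_equal(cell("los", "median", "ssi"), 47.5, tolerance = 0.1)
})

test_that("infeasible moment blocks are rejected naming the block", {
  expect_error(
    simulate_cohort(cohort_spec(n = 10, params = list(
      nonssi = list(vessels_mean = 1.1, vessels_sd = 0.9)))),
    "vessels"
  )
  expect_error(
    simulate_cohort(cohort_spec(n = 10, params = list(
      ssi = list(los_mean = 10, los_median = 20)))),
    "los"
  )
  expect_error(
    simulate_cohort(cohort_spec(n = 10, params = list(
      nonssi = list(types_mean = 3, types_sd = 0.5)))),
    "antibiotic_types"
  )
  expect_error(cohort_spec(params = list(ssi = list(male_p = 1.4))), "0, 1")
})

test_that("center B defaults differ only in size and prevalence", {
  a <- cohort_spec(center = "A")
  b <- cohort_spec(center = "B")
  expect_equal(b$n, 845L)
  expect_equal(b$prevalence, 17 / 845)
  expect_identical(a$params, b$params)
})

test_that("distribution families are swappable via the spec", {
  s <- cohort_spec(n = 500, seed = 10,
                   families = list(los = "gamma", types = "poisson"))
  co <- simulate_cohort(s)
  expect_s3_class(co, "ssi_cohort")
  expect_error(cohort_spec(families = list(los = "weibull")))
})
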