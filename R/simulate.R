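#' Specification of a synthetic CABG claims cohort
#'
#' Defines the class-conditional (SSI vs non-SSI) distributions from which a
#' synthetic cohort is drawn. The default parameter blocks reproduce the
#' published characteristics of a medical-center CABG cohort of 1,017
#' surgeries with 24 surveillance-confirmed SSIs ("center A"); `center = "B"`
#' keeps the same class-conditional blocks but uses n = 845 and prevalence
#' 17/845, since only cohort size and SSI count are reported for the
#' verification center.
#'
#' Distribution families are module choices (only class moments are reported
#' for the real cohorts): length of stay is lognormal with the scale set by
#' the class median and the shape solved from the class mean (the SSI class is
#' strongly right-skewed: mean 58.29 d, median 47.5 d); antibiotic-type counts
#' are 1 + negative binomial matched to mean/sd; doses are gamma; sex,
#' cefazolin use, second-line use and the ICD flag are Bernoulli; age is
#' normal truncated to [20, 100] (under-20 patients are excluded upstream);
#' vessels obstructed take values in {1, 2, 3} with probabilities solved from
#' the class mean/sd. Families can be swapped per block via `families`.
#' Variables are sampled independently within class: no covariance information
#' is available to calibrate a dependence structure.
#'
#' Total antibiotic dose is generated as cefazolin dose plus an independent
#' gamma non-cefazolin component whose mean and variance are solved so the
#' class-level total matches the target moments; this keeps
#' `cefazolin_ddd <= antibiotic_ddd_total` true by construction without
#' distorting the class means.
#'
#' @param n cohort size.
#' @param prevalence SSI probability (default 24/1017).
#' @param seed RNG seed.
#' @param center `"A"` (default) or `"B"` (n = 845, prevalence 17/845).
#' @param params optional list overriding entries of the per-class parameter
#'   blocks `nonssi` and `ssi` (see Details).
#' @param families optional list overriding distribution families:
#'   `los` in `c("lognormal", "gamma")`, `types` in `c("negbin", "poisson")`.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = NULL, prevalence = NULL, seed = 1L,
                        center = c("A", "B"), params = NULL, families = NULL) {
  center <- match.arg(center)
  n <- n %||% if (center == "A") 1017L else 845L
  prevalence <- prevalence %||% if (center == "A") 24 / 1017 else 17 / 845
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1)
  base <- list(
    nonssi = list(
      male_p = 781 / 993, age_mean = 64.98, age_sd = 10.86,
      vessels_mean = 1.89, vessels_sd = 0.33,
      los_mean = 17.11, los_sd = 6.60, los_median = 16,
      types_mean = 1.51, types_sd = 0.90,
      ddd_mean = 7.89, ddd_sd = 8.43,
      cefazolin_p = 975 / 993, cefazolin_dose_mean = 3.96,
      cefazolin_dose_sd = 2.12,
      second_line_p = 95 / 993, icd_p = 36 / 993
    ),
    ssi = list(
      male_p = 14 / 24, age_mean = 67.14, age_sd = 10.95,
      vessels_mean = 1.67, vessels_sd = 0.56,
      los_mean = 58.29, los_sd = 58.72, los_median = 47.5,
      types_mean = 3.71, types_sd = 2.10,
      ddd_mean = 24.07, ddd_sd = 16.84,
      cefazolin_p = 13 / 24, cefazolin_dose_mean = 2.65,
      cefazolin_dose_sd = 3.61,
      second_line_p = 20 / 24, icd_p = 9 / 24
    )
  )
  if (!is.null(params)) {
    for (cls in names(params)) {
      stopifnot(cls %in% c("nonssi", "ssi"))
      base[[cls]][names(params[[cls]])] <- params[[cls]]
    }
  }
  fam <- list(los = "lognormal", types = "negbin")
  if (!is.null(families)) fam[names(families)] <- families
  stopifnot(fam$los %in% c("lognormal", "gamma"),
            fam$types %in% c("negbin", "poisson"))
  for (cls in c("nonssi", "ssi")) {
    b <- base[[cls]]
    probs <- c(b$male_p, b$cefazolin_p, b$second_line_p, b$icd_p)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (any(c(b$age_sd, b$los_sd, b$types_sd, b$ddd_sd,
              b$cefazolin_dose_sd) < 0)) stop("standard deviations must be >= 0")
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 seed = as.integer(seed), center = center,
                 params = base, families = fam),
            class = "cohort_spec")
}

# probabilities on {1,2,3} matching a target mean/sd; errors when infeasible
#' @keywords internal
#' @noRd
solve_vessels_probs <- function(mean, sd) {
  m2 <- sd^2 + mean^2
  p3 <- (m2 - 3 * mean + 2) / 2
  p2 <- mean - 1 - 2 * p3
  p1 <- 1 - p2 - p3
  p <- c(p1, p2, p3)
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop(sprintf(
      "infeasible moment matching in block 'vessels': mean %.3f, sd %.3f", mean, sd))
  }
  pmin(pmax(p, 0), 1)
}

# gamma shape/rate from mean/sd
#' @keywords internal
#' @noRd
gamma_pars <- function(mean, sd, block) {
  if (mean <= 0 || sd <= 0) {
    stop(sprintf("infeasible moment matching in block '%s'", block))
  }
  shape <- (mean / sd)^2
  list(shape = shape, rate = shape / mean)
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n` episodes: a Bernoulli(`prevalence`) surveillance SSI label,
#' then class-conditional draws of every claims field (see [cohort_spec()]).
#' The ATC code set holds the cefazolin code for cefazolin users, one
#' uniformly chosen second-line code when the second-line indicator is drawn,
#' and a filler first-line code otherwise; the ICD indicator materializes as
#' code 998.5 among the index-hospitalization secondary diagnoses. Exclusion
#' criteria of the real cohorts (age < 20, in-hospital death, SSI from a prior
#' operation) are modeled as already applied. Identical spec and seed
#' reproduce the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @return an `ssi_cohort` with attributes `spec` and `seed`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 200, seed = 42))
#' table(cohort$ssi_label)
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  pick <- function(field) {
    # per-episode parameter vector by class
    ifelse(ssi == 1L, spec$params$ssi[[field]], spec$params$nonssi[[field]])
  }
  out <- with_seed(spec$seed, {
    ssi <- as.integer(stats::runif(n) < spec$prevalence)

    sex <- ifelse(stats::runif(n) < pick("male_p"), "male", "female")

    a_mean <- pick("age_mean"); a_sd <- pick("age_sd")
    plo <- stats::pnorm(20, a_mean, a_sd)
    phi <- stats::pnorm(100, a_mean, a_sd)
    age <- round(stats::qnorm(plo + stats::runif(n) * (phi - plo), a_mean, a_sd))

    vp_non <- solve_vessels_probs(spec$params$nonssi$vessels_mean,
                                  spec$params$nonssi$vessels_sd)
    vp_ssi <- solve_vessels_probs(spec$params$ssi$vessels_mean,
                                  spec$params$ssi$vessels_sd)
    u <- stats::runif(n)
    cum_non <- cumsum(vp_non); cum_ssi <- cumsum(vp_ssi)
    vessels <- ifelse(ssi == 1L,
                      1L + findInterval(u, cum_ssi[1:2] + 1e-15),
                      1L + findInterval(u, cum_non[1:2] + 1e-15))

    if (spec$families$los == "lognormal") {
      for (cls in c("nonssi", "ssi")) {
        b <- spec$params[[cls]]
        if (b$los_mean < b$los_median) {
          stop("infeasible moment matching in block 'los': mean below median")
        }
      }
      los_med <- pick("los_median")
      sdlog <- sqrt(2 * (log(pick("los_mean")) - log(los_med)))
      los <- stats::rlnorm(n, meanlog = log(los_med), sdlog = sdlog)
    } else {
      los_mean <- pick("los_mean")
      shape <- (los_mean / pick("los_sd"))^2
      los <- stats::rgamma(n, shape, shape / los_mean)
    }

    for (cls in c("nonssi", "ssi")) {
      b <- spec$params[[cls]]
      if (b$types_mean < 1) {
        stop("infeasible moment matching in block 'antibiotic_types': ",
             "mean count below the minimum of 1")
      }
      if (spec$families$types == "negbin" && b$types_mean > 1 &&
          b$types_sd^2 <= b$types_mean - 1) {
        stop("infeasible moment matching in block 'antibiotic_types': ",
             "variance must exceed shifted mean for the negative binomial")
      }
    }
    t_mean <- pick("types_mean") - 1
    if (spec$families$types == "negbin") {
      t_var <- pick("types_sd")^2
      size <- ifelse(t_mean > 0, t_mean^2 / pmax(t_var - t_mean, 1e-12), 1)
      types <- 1L + stats::rnbinom(n, size = size, mu = t_mean)
    } else {
      types <- 1L + stats::rpois(n, t_mean)
    }

    cef_user <- stats::runif(n) < pick("cefazolin_p")
    cef_pars_n <- gamma_pars(spec$params$nonssi$cefazolin_dose_mean,
                             spec$params$nonssi$cefazolin_dose_sd, "cefazolin")
    cef_pars_s <- gamma_pars(spec$params$ssi$cefazolin_dose_mean,
                             spec$params$ssi$cefazolin_dose_sd, "cefazolin")
    cef_shape <- ifelse(ssi == 1L, cef_pars_s$shape, cef_pars_n$shape)
    cef_rate <- ifelse(ssi == 1L, cef_pars_s$rate, cef_pars_n$rate)
    cefazolin <- ifelse(cef_user, stats::rgamma(n, cef_shape, cef_rate), 0)

    # non-cefazolin dose component solved so the class total matches targets
    rest_pars <- lapply(c("nonssi", "ssi"), function(cls) {
      b <- spec$params[[cls]]
      m <- b$ddd_mean - b$cefazolin_p * b$cefazolin_dose_mean
      v <- b$ddd_sd^2 - b$cefazolin_p * b$cefazolin_dose_sd^2 -
        b$cefazolin_p * (1 - b$cefazolin_p) * b$cefazolin_dose_mean^2
      if (m <= 0 || v <= 0) {
        stop("infeasible moment matching in block 'antibiotic_ddd_total'")
      }
      list(shape = m^2 / v, rate = m / v)
    })
    rest_shape <- ifelse(ssi == 1L, rest_pars[[2]]$shape, rest_pars[[1]]$shape)
    rest_rate <- ifelse(ssi == 1L, rest_pars[[2]]$rate, rest_pars[[1]]$rate)
    ddd_total <- cefazolin + stats::rgamma(n, rest_shape, rest_rate)

    second_line <- stats::runif(n) < pick("second_line_p")
    sl_codes <- unname(second_line_catalog())
    sl_draw <- sl_codes[sample.int(length(sl_codes), n, replace = TRUE)]
    fillers <- c("J01CA04", "J01DB01", "J01FA09", "J01EE01")
    fill_draw <- fillers[sample.int(length(fillers), n, replace = TRUE)]
    icd_flag <- stats::runif(n) < pick("icd_p")

    atc <- vector("list", n)
    idx_dx <- vector("list", n)
    for (i in seq_len(n)) {
      codes <- character(0)
      if (cef_user[i]) codes <- c(codes, cefazolin_atc())
      if (second_line[i]) codes <- c(codes, sl_draw[i])
      if (!length(codes)) codes <- fill_draw[i]
      atc[[i]] <- codes
      idx_dx[[i]] <- if (icd_flag[i]) "998.5" else character(0)
    }

    data.frame(
      patient_id = sprintf("%s%05d", spec$center, seq_len(n)),
      age = as.integer(age), sex = sex, los = los,
      vessels_obstructed = as.integer(vessels),
      antibiotic_types = as.integer(types),
      antibiotic_ddd_total = ddd_total,
      cefazolin_ddd = cefazolin,
      atc_codes_used = I(atc),
      index_secondary_dx = I(idx_dx),
      postdischarge_dx = I(replicate(n, character(0), simplify = FALSE)),
      ssi_label = ssi,
      stringsAsFactors = FALSE
    )
  })
  cohort <- as_cohort(out)
  attr(cohort, "spec") <- spec
  attr(cohort, "seed") <- spec$seed
  cohort
}

#' Per-class moment report for a cohort
#'
#' Summarizes every cohort variable by class (overall / non-SSI / SSI):
#' means and standard deviations for the continuous variables, median and IQR
#' for length of stay, and proportions for the binary indicators, mirroring
#' the layout of a cohort-characteristics table. With a single-class cohort
#' the absent class's columns are `NA` rather than an error.
#'
#' @param cohort an `ssi_cohort`.
#' @return a data frame with columns `variable`, `statistic`, `all`,
#'   `non_ssi`, `ssi`.
#' @export
moment_report <- function(cohort) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) stop("cohort is empty")
  crit <- compute_criteria(cohort)
  icd <- classify_icd9(cohort)
  vals <- list(
    male = as.numeric(cohort$sex == "male"),
    age = cohort$age,
    vessels_obstructed = cohort$vessels_obstructed,
    los = cohort$los,
    antibiotic_types = cohort$antibiotic_types,
    antibiotic_ddd_total = cohort$antibiotic_ddd_total,
    cefazolin_use = as.numeric(cohort$cefazolin_ddd > 0),
    cefazolin_ddd_users = ifelse(cohort$cefazolin_ddd > 0,
                                 cohort$cefazolin_ddd, NA_real_),
    icd9_ssi_code = as.numeric(icd$prediction),
    second_line_use = as.numeric(crit$c4_second_line)
  )
  stats_for <- function(v, stat, mask) {
    v <- v[mask]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    switch(stat,
           mean = mean(v), sd = stats::sd(v),
           median = stats::median(v), iqr = stats::IQR(v),
           proportion = mean(v))
  }
  groups <- list(all = rep(TRUE, nrow(cohort)),
                 non_ssi = cohort$ssi_label == 0L,
                 ssi = cohort$ssi_label == 1L)
  rows <- list(
    c("n", "count"), c("male", "proportion"), c("age", "mean"),
    c("age", "sd"), c("vessels_obstructed", "mean"),
    c("vessels_obstructed", "sd"), c("los", "mean"), c("los", "sd"),
    c("los", "median"), c("los", "iqr"), c("antibiotic_types", "mean"),
    c("antibiotic_types", "sd"), c("antibiotic_ddd_total", "mean"),
    c("antibiotic_ddd_total", "sd"), c("cefazolin_use", "proportion"),
    c("cefazolin_ddd_users", "mean"), c("cefazolin_ddd_users", "sd"),
    c("icd9_ssi_code", "proportion"), c("second_line_use", "proportion")
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    cells <- vapply(groups, function(mask) {
      if (r[1] == "n") return(sum(mask))
      stats_for(vals[[r[1]]], r[2], mask)
    }, numeric(1))
    data.frame(variable = r[1], statistic = r[2],
               all = cells[["all"]], non_ssi = cells[["non_ssi"]],
               ssi = cells[["ssi"]], stringsAsFactors = FALSE)
  }))
  out
}

#' Write a cohort spec as YAML (provenance record)
#'
#' @param spec a [cohort_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spec_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 17)
  invisible(path)
}
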