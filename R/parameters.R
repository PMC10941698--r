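#' Parameter set for the contraception and pregnancy model
#'
#' Bundles every parameter the monthly transition engine needs, keyed by
#' method and age. Ages are single years 15-49; several parameters vary by
#' 5-year age group ("15-19" ... "45-49"). All transition probabilities are
#' monthly. Note that the probability of pregnancy while not using
#' contraception (\code{pregnancy_not_using_in_2010}) is stored as a
#' \emph{monthly} probability and is multiplied directly by the HIV and
#' age-group scaling factors.
#'
#' @param method_use_in_2010 35 x 11 matrix (ages 15-49 by the 11 categories
#'   of \code{\link{cp_methods}}), each row a distribution over states in the
#'   baseline year; rows must sum to 1.
#' @param pregnancy_not_using_in_2010 monthly pregnancy probability for women
#'   not using contraception, by single year of age (length 35).
#' @param pregnancy_not_using_hiv_effect multiplier on the above for
#'   HIV-positive women, by 5-year age group (length 7).
#' @param age_specific_fertility_rates annual live births per woman by 5-year
#'   age group (length 7); used to schedule births in the first nine months
#'   of a simulation, before any simulated conception can have come to term.
#' @param scaling_factor_on_monthly_risk_of_pregnancy multiplier on the
#'   monthly risk of pregnancy and of contraceptive failure, by 5-year age
#'   group (length 7); the calibration target of
#'   \code{\link{fit_pregnancy_scaling_factors}}.
#' @param initiation_by_method monthly probability that a non-user starts
#'   each method: either a named length-10 vector (constant over age) or a
#'   35 x 10 matrix (ages by method). The sterilization age restriction
#'   (\code{\link{apply_sterilization_age_restriction}}) produces the
#'   age-varying form.
#' @param initiation_after_birth probability of starting each method in the
#'   month following the end of a pregnancy (length 10).
#' @param prob_switch_from monthly probability of switching away from each
#'   method, conditional on not discontinuing (length 10).
#' @param switch_matrix 10 x 10 matrix of destination probabilities given a
#'   switch; zero diagonal, rows sum to 1.
#' @param failure_by_method monthly probability of becoming pregnant while
#'   using each method (length 10).
#' @param discontinuation_by_method monthly probability of discontinuing each
#'   method (length 10).
#' @param rr_fail_under25 relative risk of method failure for women younger
#'   than 25 (default 2.2).
#' @param initiation_by_age proportional deviation of initiation probability
#'   by single year of age; the multiplier applied is \code{1 + value}.
#' @param discontinuation_by_age proportional deviation of discontinuation
#'   probability by single year of age; multiplier is \code{1 + value}.
#' @param time_age_trend_in_initiation per-year multiplicative trend applied
#'   to initiation probabilities as \code{trend^(years since baseline)}.
#' @param time_age_trend_in_stopping per-year multiplicative trend applied to
#'   discontinuation probabilities.
#' @param days_between_appts_for_maintenance named vector of days between
#'   maintenance family-planning appointments for maintainable methods.
#' @param live_birth_probability probability that a completed pregnancy is a
#'   live birth (default 1; terminations are outside this model's scope).
#' @param baseline_year calendar year the baseline probabilities refer to.
#'
#' @return An object of class \code{cp_parameters}.
#' @seealso \code{\link{generate_default_parameters}},
#'   \code{\link{validate_parameters}}, \code{\link{load_parameters}}
#' @export
cp_parameters <- function(method_use_in_2010,
                          pregnancy_not_using_in_2010,
                          pregnancy_not_using_hiv_effect,
                          age_specific_fertility_rates,
                          scaling_factor_on_monthly_risk_of_pregnancy,
                          initiation_by_method,
                          initiation_after_birth,
                          prob_switch_from,
                          switch_matrix,
                          failure_by_method,
                          discontinuation_by_method,
                          rr_fail_under25 = 2.2,
                          initiation_by_age = stats::setNames(rep(0, 35), CP_AGES),
                          discontinuation_by_age = stats::setNames(rep(0, 35), CP_AGES),
                          time_age_trend_in_initiation = 1,
                          time_age_trend_in_stopping = 1,
                          days_between_appts_for_maintenance = c(
                            IUD = 4383, implant = 1461, injection = 91,
                            male_condom = 91, other_modern = 91, pill = 91),
                          live_birth_probability = 1,
                          baseline_year = 2010) {
  if (is.null(dim(initiation_by_method))) {
    initiation_by_method <- matrix(rep(initiation_by_method[CP_USE], each = 35),
                                   nrow = 35, dimnames = list(CP_AGES, CP_USE))
  }
  p <- list(
    method_use_in_2010 = cp_as_age_table(method_use_in_2010, CP_METHODS),
    pregnancy_not_using_in_2010 = cp_as_age_vector(pregnancy_not_using_in_2010),
    pregnancy_not_using_hiv_effect =
      cp_as_group_vector(pregnancy_not_using_hiv_effect),
    age_specific_fertility_rates =
      cp_as_group_vector(age_specific_fertility_rates),
    scaling_factor_on_monthly_risk_of_pregnancy =
      cp_as_group_vector(scaling_factor_on_monthly_risk_of_pregnancy),
    initiation_by_method = cp_as_age_table(initiation_by_method, CP_USE),
    initiation_after_birth = cp_as_method_vector(initiation_after_birth),
    prob_switch_from = cp_as_method_vector(prob_switch_from),
    switch_matrix = cp_as_switch_matrix(switch_matrix),
    failure_by_method = cp_as_method_vector(failure_by_method),
    discontinuation_by_method = cp_as_method_vector(discontinuation_by_method),
    rr_fail_under25 = as.numeric(rr_fail_under25),
    initiation_by_age = cp_as_age_vector(initiation_by_age),
    discontinuation_by_age = cp_as_age_vector(discontinuation_by_age),
    time_age_trend_in_initiation = as.numeric(time_age_trend_in_initiation),
    time_age_trend_in_stopping = as.numeric(time_age_trend_in_stopping),
    days_between_appts_for_maintenance =
      days_between_appts_for_maintenance[sort(names(days_between_appts_for_maintenance))],
    live_birth_probability = as.numeric(live_birth_probability),
    baseline_year = as.integer(baseline_year))
  class(p) <- "cp_parameters"
  p
}

cp_as_age_vector <- function(x) {
  stopifnot(length(x) == 35)
  stats::setNames(as.numeric(x), CP_AGES)
}

cp_as_group_vector <- function(x) {
  stopifnot(length(x) == 7)
  stats::setNames(as.numeric(x), CP_AGE_GROUPS)
}

cp_as_method_vector <- function(x) {
  stopifnot(length(x) == 10)
  if (!is.null(names(x))) {
    stopifnot(setequal(names(x), CP_USE))
    x <- x[CP_USE]
  }
  stats::setNames(as.numeric(x), CP_USE)
}

cp_as_age_table <- function(x, cols) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == 35, ncol(x) == length(cols))
  if (!is.null(colnames(x))) {
    stopifnot(setequal(colnames(x), cols))
    x <- x[, cols, drop = FALSE]
  }
  dimnames(x) <- list(CP_AGES, cols)
  x
}

cp_as_switch_matrix <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == 10, ncol(x) == 10)
  if (!is.null(rownames(x))) x <- x[CP_USE, CP_USE]
  dimnames(x) <- list(CP_USE, CP_USE)
  x
}

#' Synthetic default parameter set
#'
#' Builds a complete, validated parameter set. Quantities for which published
#' Malawi estimates exist as printed scalars are embedded verbatim: the HIV
#' fertility multipliers (1.4, 0.9, 0.8, 0.7, 0.5, 0.4, 0.3 by age group),
#' the 2010-2014 age-specific fertility rates (0.144, 0.239, 0.213, 0.174,
#' 0.123, 0.061, 0.022), the calibrated pregnancy-risk scaling factors
#' (1.227, 0.799, 0.829, 0.809, 0.749, 0.645, 0.941), the under-25 failure
#' risk ratio 2.2 and the method-specific maintenance intervals. The
#' method-level tables (baseline method mix, monthly initiation, switching,
#' discontinuation and failure probabilities, age-effect curves) are
#' synthesized to be demographically plausible for the 2010 Malawi setting --
#' injection is the dominant and highest-initiation modern method -- and are
#' jittered reproducibly by \code{seed}. The sterilization age restriction
#' (no initiation below age 30, mass preserved) is applied.
#'
#' @param seed integer seed controlling the jitter; the same seed always
#'   yields the identical parameter set.
#' @return A validated \code{\link{cp_parameters}} object.
#' @export
#' @examples
#' p <- generate_default_parameters(seed = 1)
#' p$rr_fail_under25
generate_default_parameters <- function(seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L)

  ages <- CP_AGES

  # proportion of women using any method, by age (low at 15, peak early 30s)
  p_use <- 0.05 + 0.40 * exp(-((ages - 32) / 13)^2)

  # method shares among users; sterilization ramps in from age 30
  base_share <- c(pill = 0.07, IUD = 0.01, injection = 0.52, implant = 0.04,
                  male_condom = 0.07, female_sterilization = 0.00,
                  other_modern = 0.01, periodic_abstinence = 0.09,
                  withdrawal = 0.06, other_traditional = 0.06)
  share <- matrix(rep(base_share, each = 35), nrow = 35,
                  dimnames = list(ages, CP_USE))
  share[, "female_sterilization"] <- 0.14 * pmin(pmax(ages - 29, 0) / 15, 1)
  share <- share * matrix(exp(stats::runif(35 * 10, -0.08, 0.08)), 35, 10)
  share <- share / rowSums(share)
  method_use <- cbind(not_using = 1 - p_use, share * p_use)

  # monthly pregnancy probability while not using, by age (fecundity shape)
  preg_nu <- stats::approx(c(15, 20, 25, 30, 35, 40, 45, 49),
                           c(0.015, 0.022, 0.021, 0.019, 0.016, 0.010,
                             0.005, 0.002), xout = ages)$y

  init <- c(pill = 0.0028, IUD = 0.0004, injection = 0.0095, implant = 0.0020,
            male_condom = 0.0025, female_sterilization = 0.0007,
            other_modern = 0.0003, periodic_abstinence = 0.0018,
            withdrawal = 0.0012, other_traditional = 0.0012)
  init <- init * (1 + stats::runif(10, -0.05, 0.05))

  after_birth <- c(pill = 0.012, IUD = 0.003, injection = 0.090,
                   implant = 0.035, male_condom = 0.008,
                   female_sterilization = 0.004, other_modern = 0.002,
                   periodic_abstinence = 0.004, withdrawal = 0.002,
                   other_traditional = 0.003)

  switch_from <- c(pill = 0.020, IUD = 0.006, injection = 0.015,
                   implant = 0.008, male_condom = 0.022,
                   female_sterilization = 0, other_modern = 0.020,
                   periodic_abstinence = 0.018, withdrawal = 0.020,
                   other_traditional = 0.018)

  dest <- c(pill = 0.14, IUD = 0.03, injection = 0.45, implant = 0.12,
            male_condom = 0.10, female_sterilization = 0.02,
            other_modern = 0.02, periodic_abstinence = 0.05,
            withdrawal = 0.04, other_traditional = 0.03)
  sw <- matrix(rep(dest, each = 10), 10, dimnames = list(CP_USE, CP_USE))
  sw <- sw * matrix(exp(stats::runif(100, -0.1, 0.1)), 10, 10)
  diag(sw) <- 0
  sw <- sw / rowSums(sw)

  fail <- c(pill = 0.0040, IUD = 0.0006, injection = 0.0020,
            implant = 0.0003, male_condom = 0.0085,
            female_sterilization = 0.00005, other_modern = 0.0060,
            periodic_abstinence = 0.0120, withdrawal = 0.0130,
            other_traditional = 0.0120)

  disc <- c(pill = 0.030, IUD = 0.010, injection = 0.024, implant = 0.012,
            male_condom = 0.035, female_sterilization = 0,
            other_modern = 0.030, periodic_abstinence = 0.030,
            withdrawal = 0.034, other_traditional = 0.030)

  init_by_age <- 0.55 * exp(-0.5 * ((ages - 21) / 6)^2) - 0.25
  disc_by_age <- 0.45 - 0.018 * (ages - 15)

  p <- cp_parameters(
    method_use_in_2010 = method_use,
    pregnancy_not_using_in_2010 = preg_nu,
    pregnancy_not_using_hiv_effect = c(1.4, 0.9, 0.8, 0.7, 0.5, 0.4, 0.3),
    age_specific_fertility_rates = c(0.144, 0.239, 0.213, 0.174, 0.123,
                                     0.061, 0.022),
    scaling_factor_on_monthly_risk_of_pregnancy = c(1.227, 0.799, 0.829,
                                                    0.809, 0.749, 0.645,
                                                    0.941),
    initiation_by_method = init,
    initiation_after_birth = after_birth,
    prob_switch_from = switch_from,
    switch_matrix = sw,
    failure_by_method = fail,
    discontinuation_by_method = disc,
    rr_fail_under25 = 2.2,
    initiation_by_age = init_by_age,
    discontinuation_by_age = disc_by_age)
  apply_sterilization_age_restriction(p)
}

#' Zero out sterilization initiation below an age cut, preserving mass
#'
#' Female sterilization should not be initiated by women considered too
#' young. This transform sets the sterilization initiation probability to
#' zero below \code{eligible_age} and scales it up for older women by
#' (total weight)/(weight at or above the cut), so that the expected number
#' of sterilization initiations across the population is unchanged. Within
#' each age the other methods are rescaled multiplicatively so the total
#' initiation probability at that age is also unchanged.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @param eligible_age youngest age (years) at which sterilization may be
#'   initiated; default 30.
#' @param age_weights nonnegative weights over ages 15-49 (the population
#'   age distribution used to preserve the expectation); default uniform.
#' @return A \code{cp_parameters} object with an age-varying
#'   \code{initiation_by_method} table.
#' @export
apply_sterilization_age_restriction <- function(p, eligible_age = 30,
                                                age_weights = rep(1, 35)) {
  stopifnot(inherits(p, "cp_parameters"), length(age_weights) == 35,
            all(age_weights >= 0))
  young <- CP_AGES < eligible_age
  if (sum(age_weights[!young]) == 0)
    stop("age_weights are all zero at or above the eligibility cut")
  im <- p$initiation_by_method
  ster <- im[, "female_sterilization"]
  if (all(ster == 0)) return(p)  # nothing to redistribute

  # population sterilization mass moved onto the eligible ages; for an
  # age-constant input this is (sum of weights)/(sum of weights at or above
  # the cut), and in general it preserves the expected number of
  # sterilization initiations for any weight vector
  mass_old <- sum(age_weights * ster)
  mass_eligible <- sum(age_weights[!young] * ster[!young])
  if (mass_eligible == 0)
    stop("no sterilization initiation probability at eligible ages to ",
         "redistribute onto")
  f <- mass_old / mass_eligible
  new_ster <- ifelse(young, 0, ster * f)
  if (any(new_ster > 1))
    stop("scaled sterilization probability exceeds 1; ",
         "raise eligible_age or cap the input probability")
  total <- rowSums(im)
  other <- im[, setdiff(CP_USE, "female_sterilization"), drop = FALSE]
  other_target <- total - new_ster
  if (any(other_target < -1e-12))
    stop("scaled sterilization probability exceeds the total initiation ",
         "probability at some age; raise eligible_age")
  os <- rowSums(other)
  scale <- ifelse(os > 0, other_target / os, 1)
  im2 <- cbind(other * scale, female_sterilization = new_ster)[, CP_USE]
  p$initiation_by_method <- cp_as_age_table(im2, CP_USE)
  p
}

#' Validate a parameter set
#'
#' Checks every structural rule the engine relies on: probabilities in
#' \code{[0, 1]}, baseline method-mix rows summing to 1, switch-matrix rows
#' summing to 1 with a zero diagonal, positive failure risk ratio,
#' nonnegative fertility rates and scaling factors, positive integer
#' maintenance intervals, and age-effect deviations above -1. All violations
#' are collected, not just the first.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @return An object of class \code{cp_validation}: a list with \code{ok}
#'   (logical) and \code{violations} (data frame with columns \code{rule},
#'   \code{location}, \code{message}).
#' @export
validate_parameters <- function(p) {
  v <- list()
  bad <- function(rule, location, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, location = location,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  prob_fields <- c("method_use_in_2010", "pregnancy_not_using_in_2010",
                   "initiation_by_method", "initiation_after_birth",
                   "prob_switch_from", "switch_matrix", "failure_by_method",
                   "discontinuation_by_method", "live_birth_probability")
  for (f in prob_fields) {
    x <- p[[f]]
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      i <- which(!is.finite(x) | x < 0 | x > 1)
      bad("probability_range", paste0(f, "[", paste(i, collapse = ","), "]"),
          "probability out of range [0, 1]")
    }
  }
  mu <- rowSums(p$method_use_in_2010)
  off <- which(abs(mu - 1) > 1e-9)
  if (length(off))
    bad("method_use_rows_sum_1",
        paste0("method_use_in_2010[age ", paste(CP_AGES[off], collapse = ","), "]"),
        "method-use row does not sum to 1")
  if (any(abs(diag(p$switch_matrix)) > 0))
    bad("switch_diagonal_zero", "switch_matrix",
        "switching to the current method is not a switch")
  sr <- rowSums(p$switch_matrix)
  off <- which(abs(sr - 1) > 1e-9)
  if (length(off))
    bad("switch_rows_sum_1",
        paste0("switch_matrix[", paste(CP_USE[off], collapse = ","), "]"),
        "switch-matrix row does not sum to 1")
  if (!is.finite(p$rr_fail_under25) || p$rr_fail_under25 <= 0)
    bad("rr_fail_under25_positive", "rr_fail_under25", "must be > 0")
  if (any(p$age_specific_fertility_rates < 0))
    bad("asfr_nonnegative", "age_specific_fertility_rates", "must be >= 0")
  if (any(p$pregnancy_not_using_hiv_effect < 0))
    bad("hiv_effect_nonnegative", "pregnancy_not_using_hiv_effect",
        "must be >= 0")
  if (any(p$scaling_factor_on_monthly_risk_of_pregnancy < 0))
    bad("scaling_factor_nonnegative",
        "scaling_factor_on_monthly_risk_of_pregnancy", "must be >= 0")
  d <- p$days_between_appts_for_maintenance
  if (any(d <= 0) || any(d != round(d)))
    bad("maintenance_days_positive_integer",
        "days_between_appts_for_maintenance", "must be positive integers")
  if (any(1 + p$initiation_by_age < 0))
    bad("initiation_age_multiplier_nonnegative", "initiation_by_age",
        "1 + deviation must be >= 0")
  if (any(1 + p$discontinuation_by_age < 0))
    bad("discontinuation_age_multiplier_nonnegative", "discontinuation_by_age",
        "1 + deviation must be >= 0")
  if (p$time_age_trend_in_initiation <= 0 || p$time_age_trend_in_stopping <= 0)
    bad("trend_positive", "time_age_trend_*", "trends must be > 0")

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), location = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "cp_validation")
}

#' @export
print.cp_validation <- function(x, ...) {
  if (x$ok) cat("Parameter set valid: all checks passed.\n")
  else {
    cat("Parameter set INVALID:", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}

#' @export
print.cp_parameters <- function(x, ...) {
  cat("Contraception/pregnancy model parameters (baseline",
      x$baseline_year, "\b)\n")
  cat("  methods:", paste(CP_USE, collapse = ", "), "\n")
  cat("  mean baseline use of any method:",
      format(mean(1 - x$method_use_in_2010[, "not_using"]), digits = 3), "\n")
  cat("  rr_fail_under25:", x$rr_fail_under25,
      " live_birth_probability:", x$live_birth_probability, "\n")
  cat("  trends (initiation, stopping):", x$time_age_trend_in_initiation,
      x$time_age_trend_in_stopping, "\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

CP_PARAM_FILES <- c(
  method_use_in_2010 = "method_use_in_2010.csv",
  pregnancy_not_using_in_2010 = "pregnancy_not_using_in_2010.csv",
  pregnancy_not_using_hiv_effect = "pregnancy_not_using_hiv_effect.csv",
  age_specific_fertility_rates = "age_specific_fertility_rates.csv",
  scaling_factor_on_monthly_risk_of_pregnancy =
    "scaling_factor_on_monthly_risk_of_pregnancy.csv",
  initiation_by_method = "initiation_by_method.csv",
  initiation_after_birth = "initiation_after_birth.csv",
  prob_switch_from = "prob_switch_from.csv",
  switch_matrix = "switch_matrix.csv",
  failure_by_method = "failure_by_method.csv",
  discontinuation_by_method = "discontinuation_by_method.csv",
  initiation_by_age = "initiation_by_age.csv",
  discontinuation_by_age = "discontinuation_by_age.csv",
  days_between_appts_for_maintenance = "days_between_appts_for_maintenance.csv",
  scalars = "scalars.csv")

cp_write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a parameter set as a bundle of CSV files
#'
#' One delimited file per parameter family, with method labels as columns and
#' single-year ages as rows, plus a \code{manifest.csv} mapping parameter
#' names to files. Numbers are written with enough digits for a lossless
#' round trip through \code{\link{load_parameters}}.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @param dir directory to write into (created if needed).
#' @return The manifest path, invisibly.
#' @export
save_parameters <- function(p, dir) {
  stopifnot(inherits(p, "cp_parameters"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name, df) cp_write_csv(df, file.path(dir, CP_PARAM_FILES[[name]]))

  w("method_use_in_2010",
    data.frame(age = CP_AGES, p$method_use_in_2010, check.names = FALSE))
  w("pregnancy_not_using_in_2010",
    data.frame(age = CP_AGES, value = p$pregnancy_not_using_in_2010))
  for (nm in c("pregnancy_not_using_hiv_effect", "age_specific_fertility_rates",
               "scaling_factor_on_monthly_risk_of_pregnancy"))
    w(nm, data.frame(age_group = CP_AGE_GROUPS, value = p[[nm]]))
  w("initiation_by_method",
    data.frame(age = CP_AGES, p$initiation_by_method, check.names = FALSE))
  for (nm in c("initiation_after_birth", "prob_switch_from",
               "failure_by_method", "discontinuation_by_method"))
    w(nm, data.frame(method = CP_USE, value = p[[nm]]))
  w("switch_matrix",
    data.frame(from = CP_USE, p$switch_matrix, check.names = FALSE))
  for (nm in c("initiation_by_age", "discontinuation_by_age"))
    w(nm, data.frame(age = CP_AGES, value = p[[nm]]))
  w("days_between_appts_for_maintenance",
    data.frame(method = names(p$days_between_appts_for_maintenance),
               days = p$days_between_appts_for_maintenance))
  w("scalars",
    data.frame(parameter = c("rr_fail_under25", "live_birth_probability",
                             "time_age_trend_in_initiation",
                             "time_age_trend_in_stopping", "baseline_year"),
               value = c(p$rr_fail_under25, p$live_birth_probability,
                         p$time_age_trend_in_initiation,
                         p$time_age_trend_in_stopping, p$baseline_year)))
  manifest <- data.frame(parameter = names(CP_PARAM_FILES),
                         file = unname(CP_PARAM_FILES))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Load a parameter set from a bundle of CSV files
#'
#' Reads the bundle written by \code{\link{save_parameters}} (a directory, or
#' a path to its \code{manifest.csv}). Every table is schema-checked (file
#' present, expected columns, age rows 15-49, the exact method labels) and
#' the assembled set is run through \code{\link{validate_parameters}}; a set
#' with out-of-range probabilities is rejected.
#'
#' @param path directory containing \code{manifest.csv}, or the manifest
#'   file itself.
#' @return A validated \code{\link{cp_parameters}} object.
#' @export
load_parameters <- function(path) {
  dir <- if (dir.exists(path)) path else dirname(path)
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("parameter bundle manifest not found: ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  files <- stats::setNames(manifest$file, manifest$parameter)

  rd <- function(name, cols) {
    f <- files[[name]]
    if (is.null(f) || !file.exists(file.path(dir, f)))
      stop("missing parameter table: ", name,
           " (expected file ", if (is.null(f)) CP_PARAM_FILES[[name]] else f, ")")
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (nrow(df) == 0)
      stop("parameter table is empty: ", name, " (", f, ")")
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop("table ", name, " (", f, ") lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    df
  }
  age_tab <- function(name, value_cols) {
    df <- rd(name, c("age", value_cols))
    if (!identical(as.integer(df$age), CP_AGES))
      stop("table ", name, " must have age rows 15..49")
    as.matrix(df[, value_cols, drop = FALSE])
  }
  grp_vec <- function(name) {
    df <- rd(name, c("age_group", "value"))
    if (!identical(df$age_group, CP_AGE_GROUPS))
      stop("table ", name, " must have age-group rows ",
           paste(CP_AGE_GROUPS, collapse = ", "))
    df$value
  }
  method_vec <- function(name) {
    df <- rd(name, c("method", "value"))
    stats::setNames(df$value, df$method)[CP_USE]
  }

  scal <- rd("scalars", c("parameter", "value"))
  sget <- function(k) {
    i <- match(k, scal$parameter)
    if (is.na(i)) stop("scalars table lacks parameter: ", k)
    scal$value[i]
  }
  days <- rd("days_between_appts_for_maintenance", c("method", "days"))

  p <- cp_parameters(
    method_use_in_2010 = age_tab("method_use_in_2010", CP_METHODS),
    pregnancy_not_using_in_2010 =
      age_tab("pregnancy_not_using_in_2010", "value")[, 1],
    pregnancy_not_using_hiv_effect = grp_vec("pregnancy_not_using_hiv_effect"),
    age_specific_fertility_rates = grp_vec("age_specific_fertility_rates"),
    scaling_factor_on_monthly_risk_of_pregnancy =
      grp_vec("scaling_factor_on_monthly_risk_of_pregnancy"),
    initiation_by_method = age_tab("initiation_by_method", CP_USE),
    initiation_after_birth = method_vec("initiation_after_birth"),
    prob_switch_from = method_vec("prob_switch_from"),
    switch_matrix = {
      df <- rd("switch_matrix", c("from", CP_USE))
      m <- as.matrix(df[, CP_USE])
      rownames(m) <- df$from
      m
    },
    failure_by_method = method_vec("failure_by_method"),
    discontinuation_by_method = method_vec("discontinuation_by_method"),
    rr_fail_under25 = sget("rr_fail_under25"),
    initiation_by_age = age_tab("initiation_by_age", "value")[, 1],
    discontinuation_by_age = age_tab("discontinuation_by_age", "value")[, 1],
    time_age_trend_in_initiation = sget("time_age_trend_in_initiation"),
    time_age_trend_in_stopping = sget("time_age_trend_in_stopping"),
    days_between_appts_for_maintenance = stats::setNames(days$days, days$method),
    live_birth_probability = sget("live_birth_probability"),
    baseline_year = sget("baseline_year"))

  val <- validate_parameters(p)
  if (!val$ok)
    stop("loaded parameter set fails validation:\n",
         paste(sprintf("  [%s] %s: %s", val$violations$rule,
                       val$violations$location, val$violations$message),
               collapse = "\n"))
  p
}
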