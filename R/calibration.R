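# Deterministic expectation-mode companion of the stochastic engine:
# propagates expected state fractions for 35 single-year age cohorts of
# women (11 method states, a 9-month pregnancy pipeline, and a postpartum
# slot) with fixed cohort sizes. Used inside calibration loops, where a
# smooth, noise-free objective matters more than demographic feedback;
# final verification belongs to the stochastic engine.
cp_expect_run <- function(p, n_by_age, start_year, n_years, iv = NULL) {
  ages <- CP_AGES
  g <- cp_age_group(ages)
  sf <- p$scaling_factor_on_monthly_risk_of_pregnancy[g]
  lbp <- p$live_birth_probability
  rr <- ifelse(ages < 25, p$rr_fail_under25, 1)
  Fm <- pmin(outer(rr * sf, p$failure_by_method), 1)       # 35 x 10
  s_from <- p$prob_switch_from
  s_from["female_sterilization"] <- 0
  W <- p$switch_matrix
  p_preg <- pmin(p$pregnancy_not_using_in_2010 * sf, 1)
  asfr <- p$age_specific_fertility_rates[g]

  S <- p$method_use_in_2010
  sched <- pmin(asfr / 12 * 9, 1)
  S <- S * (1 - sched)
  P <- matrix(sched / 9, 35, 9)  # one slice resolving per month
  PP <- rep(0, 35)

  months <- cp_ym(start_year, 1):(cp_ym(start_year + n_years, 1) - 1L)
  births_m <- numeric(length(months))
  pp_in <- stats::setNames(rep(0, 10), CP_USE)
  pp_total <- 0

  for (k in seq_along(months)) {
    ym <- months[k]
    if (k > 1L && cp_ym_month(ym) == 1L) {
      # cohorts age one year; 15-year-olds enter using nothing
      S[2:35, ] <- S[1:34, ]; S[1, ] <- c(1, rep(0, 10))
      P[2:35, ] <- P[1:34, ]; P[1, ] <- 0
      PP[2:35] <- PP[1:34]; PP[1] <- 0
    }
    t_yr <- (ym - cp_ym(p$baseline_year)) / 12
    I <- initiation_probabilities(p, ages, ym, iv)
    tot <- p_preg + rowSums(I)
    sc <- ifelse(tot > 1, 1 / tot, 1)
    D <- pmin(outer(1 + p$discontinuation_by_age,
                    p$discontinuation_by_method) *
                p$time_age_trend_in_stopping^t_yr, 1)
    D[, "female_sterilization"] <- 0

    U <- S[, CP_USE, drop = FALSE]
    fail_out <- U * Fm
    rem <- U - fail_out
    disc_out <- rem * D
    rem2 <- rem - disc_out
    sw_out <- rem2 * rep(s_from, each = 35)
    arrivals <- sw_out %*% W

    nu <- S[, 1]
    preg_out <- nu * p_preg * sc
    init_out <- nu * I * sc

    resolved <- P[, 9]
    births_m[k] <- sum(n_by_age * resolved * lbp)
    ppr <- postpartum_probabilities(p, ym, iv)
    pp_go <- outer(PP, ppr)
    pp_in <- pp_in + colSums(n_by_age * pp_go)
    pp_total <- pp_total + sum(n_by_age * PP)

    S[, 1] <- nu - preg_out - rowSums(init_out) + rowSums(disc_out) +
      PP * (1 - sum(ppr))
    S[, CP_USE] <- U - fail_out - disc_out - sw_out + arrivals + init_out +
      pp_go
    P[, 2:9] <- P[, 1:8]
    P[, 1] <- preg_out + rowSums(fail_out)
    PP <- resolved
  }

  yearly <- tapply(births_m, cp_ym_year(months), sum)
  mix <- colSums(n_by_age * S) / sum(n_by_age)
  list(yearly_births = data.frame(year = as.integer(names(yearly)),
                                  value = as.numeric(yearly)),
       final_mix = mix,
       postpartum_shares = if (pp_total > 0) pp_in / pp_total else pp_in * 0)
}

# women counts by single year of age 15-49 implied by a configuration
cp_women_by_age <- function(config) {
  as_ <- config$age_structure
  w <- as_[as_$sex == "F" & as_$age >= 15 & as_$age <= 49, ]
  n <- stats::setNames(rep(0, 35), CP_AGES)
  n[as.character(w$age)] <- w$prop * config$n_agents
  n
}

#' Calibration result
#'
#' Common return type of the fitting routines: fitted values, the
#' achieved-versus-target table, a convergence flag and the iteration count.
#' \code{coef()} extracts the fitted vector.
#'
#' @name cp_calibration
NULL

cp_calibration <- function(fitted, achieved, target, converged, iterations,
                           what, extra = list()) {
  if (is.null(names(target))) names(target) <- as.character(seq_along(target))
  structure(c(list(fitted = fitted,
                   table = data.frame(name = names(target),
                                      target = as.numeric(target),
                                      achieved = as.numeric(achieved)),
                   converged = converged, iterations = iterations,
                   what = what), extra),
            class = "cp_calibration")
}

#' @export
print.cp_calibration <- function(x, ...) {
  cat("Calibration:", x$what, "\n")
  cat("  converged:", x$converged, "after", x$iterations, "iteration(s)\n")
  cat("  fitted values:\n")
  print(round(x$fitted, 4))
  cat("  achieved vs target:\n")
  print(transform(x$table, target = signif(target, 5),
                  achieved = signif(achieved, 5)))
  invisible(x)
}

#' @export
coef.cp_calibration <- function(object, ...) object$fitted

#' Fit the age-group scaling factors on the monthly risk of pregnancy
#'
#' The scaling factor multiplies both the pregnancy risk of non-users and
#' every method's failure risk. It is fitted so that, at the start of the
#' simulation and given the baseline pattern of contraceptive use, the
#' expected age-specific monthly probability of a live birth matches the
#' target fertility schedule. Because the achieved probability is linear in
#' the factor, iterative proportional fitting (factor times target/achieved)
#' converges essentially in one step per group.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @param target_asfr target annual live-birth rate per woman by 5-year age
#'   group (length 7); the monthly target is this divided by 12.
#' @param sim optional \code{\link{cp_config}}; its female age structure
#'   weights the single-year ages within each group (uniform if omitted).
#' @param tol relative tolerance on each group's achieved-vs-target gap.
#' @param max_iter iteration cap.
#' @return A \code{\link{cp_calibration}} with the fitted length-7 factor
#'   vector; \code{$parameters} carries a copy of \code{p} with the fitted
#'   factors installed.
#' @export
fit_pregnancy_scaling_factors <- function(p, target_asfr, sim = NULL,
                                          tol = 0.01, max_iter = 200) {
  stopifnot(length(target_asfr) == 7)
  w <- if (is.null(sim)) stats::setNames(rep(1, 35), CP_AGES) else
    cp_women_by_age(sim)
  ages <- CP_AGES
  g <- cp_age_group(ages)
  rr <- ifelse(ages < 25, p$rr_fail_under25, 1)
  mix <- p$method_use_in_2010
  # per-age monthly conception probability per unit scaling factor
  base <- mix[, "not_using"] * p$pregnancy_not_using_in_2010 +
    rowSums(mix[, CP_USE, drop = FALSE] *
              outer(rr, p$failure_by_method))
  target_m <- target_asfr / 12
  sf <- p$scaling_factor_on_monthly_risk_of_pregnancy
  wg <- as.numeric(tapply(w, g, sum))
  achieved <- function(sf) {
    mpb <- pmin(base * sf[g], 1) * p$live_birth_probability
    ifelse(wg > 0, as.numeric(tapply(w * mpb, g, sum)) / wg, NA_real_)
  }
  live <- wg > 0  # groups with no women are left untouched
  it <- 0L
  repeat {
    it <- it + 1L
    a <- achieved(sf)
    if (any(live & a == 0 & target_m > 0))
      stop("cannot reach a positive target with zero achieved births in ",
           "group ", paste(CP_AGE_GROUPS[live & a == 0 & target_m > 0],
                           collapse = ", "))
    gap <- ifelse(live,
                  ifelse(target_m > 0, abs(a - target_m) / target_m, abs(a)),
                  0)
    if (all(gap < tol) || it > max_iter) break
    upd <- ifelse(live & target_m > 0 & a > 0, target_m / a, 1)
    sf <- sf * upd
  }
  p$scaling_factor_on_monthly_risk_of_pregnancy <- cp_as_group_vector(sf)
  cp_calibration(stats::setNames(sf, CP_AGE_GROUPS), a, target_m,
                 all(gap < tol), it, "pregnancy-risk scaling factors",
                 extra = list(parameters = p))
}

#' Fit the secular trends in starting and stopping contraception
#'
#' Searches the two per-year trend multipliers (on initiation and on
#' discontinuation) that minimize the RMSD between the model's yearly
#' live-birth trajectory and a target trajectory. The objective is evaluated
#' with the deterministic expectation-mode model, so the fit is smooth and
#' reproducible; coordinate descent over each trend is followed by a
#' Nelder-Mead polish.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @param target_births data frame (\code{year}, \code{value}) of target
#'   births per year, spanning the simulated years.
#' @param sim a \code{\link{cp_config}} giving the population size, age
#'   structure and simulated span.
#' @param tol relative RMSD (RMSD over mean target births) below which the
#'   fit is declared converged.
#' @param interval search interval for each trend multiplier.
#' @return A \code{\link{cp_calibration}} with fitted
#'   \code{c(initiation, stopping)}; \code{$rmsd} holds the achieved RMSD
#'   and \code{$parameters} a copy of \code{p} with the trends installed.
#' @export
fit_time_trends <- function(p, target_births, sim, tol = 0.01,
                            interval = c(0.9, 1.1)) {
  n_by_age <- cp_women_by_age(sim)
  n_years <- sim$end_year - sim$start_year + 1L
  run_years <- function(pp) {
    yb <- cp_expect_run(pp, n_by_age, sim$start_year, n_years)$yearly_births
    merge(yb, target_births, by = "year", suffixes = c("_model", "_target"))
  }
  objective <- function(theta) {
    pp <- p
    pp$time_age_trend_in_initiation <- theta[1]
    pp$time_age_trend_in_stopping <- theta[2]
    m <- run_years(pp)
    sqrt(mean((m$value_model - m$value_target)^2))
  }
  theta <- c(p$time_age_trend_in_initiation, p$time_age_trend_in_stopping)
  f_cur <- objective(theta)
  it <- 0L
  for (sweep in 1:8) {
    moved <- 0
    for (j in 1:2) {
      it <- it + 1L
      o <- stats::optimize(function(x) {
        th <- theta; th[j] <- x; objective(th)
      }, interval = interval, tol = 1e-5)
      moved <- moved + abs(o$minimum - theta[j])
      theta[j] <- o$minimum
      f_cur <- o$objective
    }
    if (moved < 1e-5) break
  }
  pol <- stats::optim(theta, objective, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  if (pol$value <= f_cur) { theta <- pol$par; f_cur <- pol$value }

  pp <- p
  pp$time_age_trend_in_initiation <- theta[1]
  pp$time_age_trend_in_stopping <- theta[2]
  m <- run_years(pp)
  rel <- f_cur / mean(m$value_target)
  cp_calibration(c(initiation = theta[1], stopping = theta[2]),
                 achieved = stats::setNames(m$value_model, m$year),
                 target = stats::setNames(m$value_target, m$year),
                 converged = rel < tol, iterations = it,
                 "secular trends in starting/stopping contraception",
                 extra = list(rmsd = f_cur, parameters = pp))
}

#' RMSD fit metric as a percentage of a reference deviation
#'
#' Quantifies model fit to a reference trajectory on the scale of the
#' spread between two published projection variants:
#' \code{100 * RMSD(model, reference) / RMSD(alt_reference, reference)}.
#'
#' @param model,reference,alt_reference numeric vectors over the same years,
#'   or data frames (\code{year}, \code{value}) sharing the same years.
#' @return The percentage (0 when the model equals the reference, 100 when
#'   it deviates as much as the alternative variant does).
#' @export
#' @examples
#' rmsd_fit_percentage(c(12, 10), c(10, 10), c(14, 10))  # 50
rmsd_fit_percentage <- function(model, reference, alt_reference) {
  pick <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("year", "value") %in% names(x)))
      x[order(x$year), ]
    } else data.frame(year = seq_along(x), value = as.numeric(x))
  }
  m <- pick(model); r <- pick(reference); a <- pick(alt_reference)
  if (!identical(m$year, r$year) || !identical(a$year, r$year))
    stop("all three series must share the same years")
  rmsd <- function(x, y) sqrt(mean((x - y)^2))
  denom <- rmsd(a$value, r$value)
  if (denom == 0)
    stop("reference and alternative variant are identical: metric undefined")
  100 * rmsd(m$value, r$value) / denom
}

#' Calibrate intervention multipliers to a target method mix
#'
#' Fits the Pop multipliers (and optionally the PPFP multipliers) so that
#' the share of women using each targeted modern method at the simulation
#' horizon matches the target. Each iteration runs the expectation-mode
#' model with the current intervention and applies a proportional update,
#' multiplier times target share over achieved share; PPFP multipliers are
#' updated against achieved postpartum-initiation shares analogously.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @param target_mix named target shares (proportion of women 15-49 using
#'   each method at the horizon); modern methods only.
#' @param sim a \code{\link{cp_config}} whose \code{intervention} supplies
#'   the start date (multipliers are refitted from 1).
#' @param tol relative tolerance on each achieved share.
#' @param target_ppfp optional named target postpartum-initiation shares.
#' @param max_iter iteration cap.
#' @return A \code{\link{cp_calibration}}; \code{$intervention} is the
#'   fitted \code{\link{cp_intervention}}.
#' @export
calibrate_intervention_multipliers <- function(p, target_mix, sim,
                                               tol = 0.01,
                                               target_ppfp = NULL,
                                               max_iter = 200) {
  stopifnot(all(names(target_mix) %in% CP_MODERN),
            all(target_mix >= 0 & target_mix <= 1))
  start_ym <- if (!is.null(sim$intervention)) sim$intervention$start_ym else
    cp_ym(2023, 1)
  n_by_age <- cp_women_by_age(sim)
  n_years <- sim$end_year - sim$start_year + 1L
  pop_m <- stats::setNames(rep(1, 10), CP_USE)
  ppfp_m <- stats::setNames(rep(1, 10), CP_USE)
  tgt <- names(target_mix)
  it <- 0L
  repeat {
    it <- it + 1L
    iv <- cp_intervention(pop = pop_m[CP_MODERN], ppfp = ppfp_m[CP_MODERN],
                          start_year = cp_ym_year(start_ym),
                          start_month = cp_ym_month(start_ym))
    r <- cp_expect_run(p, n_by_age, sim$start_year, n_years, iv = iv)
    ach <- r$final_mix[tgt]
    zero <- ach == 0 & target_mix > 0
    if (any(zero)) {
      base0 <- colSums(p$initiation_by_method[, tgt[zero], drop = FALSE]) == 0
      if (any(base0))
        stop("target share unreachable for method(s) with zero base ",
             "initiation: ", paste(tgt[zero][base0], collapse = ", "))
    }
    gap <- abs(ach - target_mix) / pmax(target_mix, 1e-12)
    ach_pp <- NULL
    gap_pp <- 0
    if (!is.null(target_ppfp)) {
      ach_pp <- r$postpartum_shares[names(target_ppfp)]
      gap_pp <- abs(ach_pp - target_ppfp) / pmax(target_ppfp, 1e-12)
    }
    if ((all(gap < tol) && all(gap_pp < tol)) || it >= max_iter) break
    pop_m[tgt] <- pop_m[tgt] * ifelse(ach > 0, target_mix / ach, 2)
    if (!is.null(target_ppfp))
      ppfp_m[names(target_ppfp)] <- ppfp_m[names(target_ppfp)] *
        ifelse(ach_pp > 0, target_ppfp / ach_pp, 2)
  }
  fitted <- pop_m[tgt]
  names(fitted) <- paste0("pop.", tgt)
  if (!is.null(target_ppfp)) {
    fp <- ppfp_m[names(target_ppfp)]
    names(fp) <- paste0("ppfp.", names(target_ppfp))
    fitted <- c(fitted, fp)
  }
  cp_calibration(fitted,
                 achieved = c(ach, ach_pp),
                 target = c(target_mix,
                            if (!is.null(target_ppfp)) target_ppfp),
                 converged = all(gap < tol) && all(gap_pp < tol),
                 iterations = it, "intervention multipliers",
                 extra = list(intervention = cp_intervention(
                   pop = pop_m[CP_MODERN], ppfp = ppfp_m[CP_MODERN],
                   start_year = cp_ym_year(start_ym),
                   start_month = cp_ym_month(start_ym))))
}
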