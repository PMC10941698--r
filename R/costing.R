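#' Consumable packages per contraception appointment
#'
#' The health-system consumables dispensed per case for each modern method,
#' with expected units per case and 2021 unit prices in Malawi Kwacha (MWK),
#' as assembled for costing the national health benefits package. The
#' \code{"initiation"} package is the pregnancy slide test performed when a
#' method is started. Pill and implant unit costs are weighted averages over
#' the product alternatives in use (see \code{\link{weighted_unit_cost}}).
#' Traditional methods consume no commodities.
#'
#' @return Data frame with columns \code{package}, \code{item},
#'   \code{units}, \code{unit_cost_mwk}.
#' @export
cp_consumables <- function() {
  rbind(
    data.frame(package = "initiation", item = "pregnancy slide test kit",
               units = 1, unit_cost_mwk = 32),
    data.frame(package = "pill",
               item = "oral contraceptive cycle (weighted alternatives)",
               units = 3.75, unit_cost_mwk = 493),
    data.frame(package = "IUD",
               item = c("gloves, disposable pair", "IUD, Copper T-380A"),
               units = c(2, 1), unit_cost_mwk = c(37, 26)),
    data.frame(package = "injection",
               item = c("medroxyprogesterone 150 mg vial + syringe",
                        "gloves, disposable pair", "water for injection",
                        "povidone iodine sachet", "gauze swabs"),
               units = c(1, 1, 1, 1, 1),
               unit_cost_mwk = c(481, 37, 32, 85, 16)),
    data.frame(package = "implant",
               item = c("gauze swabs", "implant rods (weighted alternatives)",
                        "trocar", "syringe, needle + swab",
                        "needle suture", "lidocaine ampoule",
                        "gloves, disposable pair", "povidone iodine sachet"),
               units = c(1, 1, 0.1, 2, 1, 2, 3, 1),
               unit_cost_mwk = c(16, 760, 312, 200, 179, 310, 37, 85)),
    data.frame(package = "male_condom", item = "condom, male",
               units = 30, unit_cost_mwk = 21),
    data.frame(package = "female_sterilization",
               item = c("povidone iodine sachet", "paracetamol 500 mg tablet",
                        "gloves, surgeon sterile pair", "tape, adhesive roll",
                        "catgut chromic suture", "gauze swabs",
                        "syringe autodestruct + alcohol swabs",
                        "diazepam ampoule", "atropine sulphate ampoule",
                        "lidocaine ampoule", "cotton wool 500 g",
                        "polyamide monofilament suture"),
               units = c(2, 8, 2, 0.25, 3, 2, 3, 1, 0.5, 1, 0.2, 3),
               unit_cost_mwk = c(85, 4, 302, 1558, 307, 16, 154, 130, 121,
                                 310, 2690, 179)),
    data.frame(package = "other_modern", item = "condom, female",
               units = 30, unit_cost_mwk = 22))
}

#' Weighted average unit cost over product alternatives
#'
#' When a method is delivered with more than one product (for example two
#' pill formulations given to 80 and 20 percent of users), the package uses
#' the share-weighted cost: sum of share x units-per-case x unit cost.
#'
#' @param alternatives data frame with columns \code{unit_cost},
#'   \code{share}, \code{units}; shares must sum to 1.
#' @return Cost per case in MWK (unrounded; round to the nearest MWK for
#'   table display).
#' @export
#' @examples
#' # two pill formulations, 80/20 split
#' weighted_unit_cost(data.frame(unit_cost = c(531.1, 340.4),
#'                               share = c(0.8, 0.2), units = 1))
weighted_unit_cost <- function(alternatives) {
  stopifnot(all(c("unit_cost", "share", "units") %in% names(alternatives)))
  if (abs(sum(alternatives$share) - 1) > 1e-9)
    stop("alternative shares must sum to 1")
  sum(alternatives$share * alternatives$units * alternatives$unit_cost)
}

#' Cost of one consumable package
#'
#' @param method a package name: a modern method or \code{"initiation"}.
#' @param packages consumables table (\code{\link{cp_consumables}}).
#' @return MWK per appointment: sum over items of expected units times unit
#'   cost.
#' @export
#' @examples
#' package_cost("injection")  # 651 MWK
package_cost <- function(method, packages = cp_consumables()) {
  rows <- packages[packages$package == method, ]
  if (!method %in% packages$package)
    stop("no consumable package for: ", method)
  sum(rows$units * rows$unit_cost_mwk)
}

#' Is a maintenance family-planning appointment due?
#'
#' A user keeps her method between appointments; a new appointment (and its
#' consumable package) is needed only when the days elapsed since the last
#' one strictly exceed the method-specific maintenance interval. A missing
#' last-appointment date is treated as due: the initiation appointment.
#'
#' @param days_elapsed days since the last family-planning appointment
#'   (\code{NA} if never attended).
#' @param method method label; must be maintainable (present in
#'   \code{days_between_appts_for_maintenance}).
#' @param p a \code{\link{cp_parameters}} object.
#' @return Logical (vectorized over \code{days_elapsed}).
#' @export
#' @examples
#' p <- generate_default_parameters(1)
#' maintenance_due(91, "injection", p)  # FALSE: not strictly greater
#' maintenance_due(92, "injection", p)  # TRUE
maintenance_due <- function(days_elapsed, method, p) {
  d <- p$days_between_appts_for_maintenance
  if (!all(method %in% names(d)))
    stop("not a maintainable method: ",
         paste(setdiff(method, names(d)), collapse = ", "))
  is.na(days_elapsed) | days_elapsed > d[method]
}

#' Convert MWK to USD
#'
#' @param amount_mwk amount in 2021 Malawi Kwacha.
#' @param mwk_per_usd exchange rate (default 790 MWK per USD, the 2021
#'   rate used throughout the costing).
#' @return Amount in USD (unrounded; unit costs are displayed to 2
#'   decimals).
#' @export
#' @examples
#' round(convert_currency(1558), 2)  # 1.97
convert_currency <- function(amount_mwk, mwk_per_usd = 790) {
  amount_mwk / mwk_per_usd
}

#' Costing configuration
#'
#' @param mwk_per_usd 2021 exchange rate, MWK per USD.
#' @param base_annual_cost_pop_mwk2021 annual national implementation cost
#'   of the population-wide demand-creation intervention, in 2021 MWK
#'   (default 2.4 billion).
#' @param base_annual_cost_ppfp_mwk2021 annual national implementation cost
#'   of the postpartum family-planning intervention, in 2021 MWK (default
#'   264 million).
#' @param base_population_15_49 the population aged 15-49 the base annual
#'   costs refer to (the 2016 level); implementation costs scale
#'   proportionally with the simulated 15-49 population. \code{NULL} lets
#'   \code{\link{summarize_costs}} use the simulated 2016 value.
#' @param total_health_expenditure_usd_per_capita total health expenditure
#'   per capita per year in USD, used to express costs as a share of health
#'   spending (default 34.4).
#' @return A list of class \code{cp_cost_config}.
#' @export
cp_cost_config <- function(mwk_per_usd = 790,
                           base_annual_cost_pop_mwk2021 = 2400e6,
                           base_annual_cost_ppfp_mwk2021 = 264e6,
                           base_population_15_49 = NULL,
                           total_health_expenditure_usd_per_capita = 34.4) {
  stopifnot(mwk_per_usd > 0, base_annual_cost_pop_mwk2021 > 0,
            base_annual_cost_ppfp_mwk2021 > 0,
            total_health_expenditure_usd_per_capita > 0)
  structure(list(mwk_per_usd = mwk_per_usd,
                 base_annual_cost_pop_mwk2021 = base_annual_cost_pop_mwk2021,
                 base_annual_cost_ppfp_mwk2021 = base_annual_cost_ppfp_mwk2021,
                 base_population_15_49 = base_population_15_49,
                 total_health_expenditure_usd_per_capita =
                   total_health_expenditure_usd_per_capita),
            class = "cp_cost_config")
}

#' Annual intervention implementation cost, scaled by population
#'
#' The base annual national cost refers to the 15-49 population of the base
#' year; each simulated intervention year is scaled proportionally to the
#' current 15-49 population.
#'
#' @param year calendar year (used only for labeling).
#' @param population_15_49 population aged 15-49 (both sexes) in that year.
#' @param cc a \code{\link{cp_cost_config}} with
#'   \code{base_population_15_49} set.
#' @param which \code{"Pop"} or \code{"PPFP"}.
#' @return Cost in 2021 MWK.
#' @export
implementation_cost <- function(year, population_15_49, cc,
                                which = c("Pop", "PPFP")) {
  which <- match.arg(which)
  stopifnot(population_15_49 > 0, !is.null(cc$base_population_15_49))
  base <- if (which == "Pop") cc$base_annual_cost_pop_mwk2021 else
    cc$base_annual_cost_ppfp_mwk2021
  base * population_15_49 / cc$base_population_15_49
}

cp_parse_period <- function(x) {
  if (is.character(x)) as.integer(strsplit(x, "-")[[1]]) else as.integer(x)
}

#' Contraception usage and cost summary by period
#'
#' For each period and modern method: the mean percentage of women 15-49
#' using the method, the corresponding number of users scaled to the
#' national population, and the consumable costs accrued at initiation and
#' maintenance appointments. Implementation costs of active interventions
#' are added per year, scaled by the 15-49 population. Accounting is in
#' MWK (2021 prices) with USD alongside; rounding (0.1 percent, nearest
#' thousand users) is applied only in the printed display.
#'
#' @param result a \code{\link{run_simulation}} result.
#' @param periods list of periods, each \code{"2023-2030"} or
#'   \code{c(2023, 2030)} (inclusive years).
#' @param cc a \code{\link{cp_cost_config}}.
#' @param packages consumables table (\code{\link{cp_consumables}}).
#' @return A list of class \code{cp_cost_summary}: \code{usage} (period x
#'   method percentages and user counts), \code{ledger} (period x category
#'   MWK and USD, with modern-methods, implementation and grand totals) and
#'   \code{scale} (the national scaling factor applied).
#' @export
summarize_costs <- function(result, periods, cc = cp_cost_config(),
                            packages = cp_consumables()) {
  stopifnot(inherits(result, "cp_sim"))
  s <- result$series
  ev <- result$events
  scale <- if (is.null(result$config$scale_target_population)) 1 else
    result$config$scale_target_population / result$config$n_agents
  iv <- result$config$intervention
  if (is.null(cc$base_population_15_49)) {
    jun <- s$n_15_49[s$year == 2016 & s$month == 6]
    if (!length(jun)) jun <- s$n_15_49[1]
    cc$base_population_15_49 <- jun * scale
  }
  init_cost <- vapply(CP_MODERN, package_cost, numeric(1),
                      packages = packages) + package_cost("initiation", packages)
  maint_cost <- vapply(CP_MODERN, package_cost, numeric(1),
                       packages = packages)

  usage <- list(); ledger <- list()
  for (pr in periods) {
    yr <- cp_parse_period(pr)
    lab <- paste0(yr[1], "-", yr[2])
    inside <- s$year >= yr[1] & s$year <= yr[2]
    if (!any(inside)) stop("period ", lab, " outside the simulated span")
    sm <- s[inside, ]
    ev_in <- ev[cp_ym_year(ev$month) >= yr[1] & cp_ym_year(ev$month) <= yr[2], ]
    for (m in CP_MODERN) {
      share <- mean(sm[[m]] / sm$women_1549)
      users <- mean(sm[[m]]) * scale
      n_init <- sum(ev_in$kind == "initiation_appt" & ev_in$to == m)
      n_maint <- sum(ev_in$kind == "maintenance_appt" & ev_in$to == m)
      mwk <- (n_init * init_cost[m] + n_maint * maint_cost[m]) * scale
      usage[[length(usage) + 1L]] <-
        data.frame(period = lab, method = m, pct_using = 100 * share,
                   users = users, initiation_appts = n_init * scale,
                   maintenance_appts = n_maint * scale)
      ledger[[length(ledger) + 1L]] <-
        data.frame(period = lab, category = m, mwk = mwk)
    }
    modern <- sum(vapply(ledger, function(d)
      if (d$period == lab && d$category %in% CP_MODERN) d$mwk else 0,
      numeric(1)))
    ledger[[length(ledger) + 1L]] <-
      data.frame(period = lab, category = "modern_total", mwk = modern)
    imp_pop <- imp_ppfp <- 0
    if (!is.null(iv)) {
      iv_start <- cp_ym_year(iv$start_ym)
      for (y in max(yr[1], iv_start):yr[2]) {
        if (y < iv_start) next
        jun <- s$n_15_49[s$year == y & s$month == 6]
        if (!length(jun)) jun <- s$n_15_49[s$year == y][1]
        imp_pop <- imp_pop + implementation_cost(y, jun * scale, cc, "Pop")
        imp_ppfp <- imp_ppfp + implementation_cost(y, jun * scale, cc, "PPFP")
      }
    }
    ledger[[length(ledger) + 1L]] <-
      data.frame(period = lab, category = "Pop_implementation", mwk = imp_pop)
    ledger[[length(ledger) + 1L]] <-
      data.frame(period = lab, category = "PPFP_implementation",
                 mwk = imp_ppfp)
    ledger[[length(ledger) + 1L]] <-
      data.frame(period = lab, category = "implementation_total",
                 mwk = imp_pop + imp_ppfp)
    ledger[[length(ledger) + 1L]] <-
      data.frame(period = lab, category = "grand_total",
                 mwk = modern + imp_pop + imp_ppfp)
  }
  usage <- do.call(rbind, usage)
  ledger <- do.call(rbind, ledger)
  ledger$usd <- convert_currency(ledger$mwk, cc$mwk_per_usd)
  structure(list(usage = usage, ledger = ledger, scale = scale),
            class = "cp_cost_summary")
}

#' @export
print.cp_cost_summary <- function(x, ...) {
  cat("Contraception usage and costs (scaled x",
      format(x$scale, digits = 4), "\b)\n")
  u <- x$usage
  u$pct_using <- round(u$pct_using, 1)                 # nearest 0.1 percent
  u$users_thousands <- round(u$users / 1000)           # nearest 1,000 users
  print(u[, c("period", "method", "pct_using", "users_thousands")],
        row.names = FALSE)
  l <- x$ledger
  l$mwk_millions <- round(l$mwk / 1e6)
  l$usd_thousands <- round(l$usd / 1e3)
  cat("\nCosts (millions MWK / thousands USD):\n")
  print(l[, c("period", "category", "mwk_millions", "usd_thousands")],
        row.names = FALSE)
  invisible(x)
}

#' Per-capita cost summary
#'
#' Expresses an additional intervention cost as USD per capita per year over
#' a period, and as a percentage of total health expenditure per capita.
#'
#' @param additional_cost_usd total additional cost over the period, USD.
#' @param mean_population mean population over the period.
#' @param years length of the period in years.
#' @param cc a \code{\link{cp_cost_config}}.
#' @return Named vector: \code{usd_per_capita_per_year} and
#'   \code{pct_of_total_health_expenditure} (unrounded; display to $0.01
#'   and 0.1 points).
#' @export
#' @examples
#' per_capita_summary(231.2e6, 26948785, 28)
per_capita_summary <- function(additional_cost_usd, mean_population, years,
                               cc = cp_cost_config()) {
  stopifnot(mean_population > 0, years > 0)
  per_cap <- additional_cost_usd / (mean_population * years)
  c(usd_per_capita_per_year = per_cap,
    pct_of_total_health_expenditure =
      100 * per_cap / cc$total_health_expenditure_usd_per_capita)
}
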