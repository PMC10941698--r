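#' Method-mix time series
#'
#' Proportion of women 15-49 in each contraception state per simulated
#' month, \code{not_using} included, so each row sums to 1. Proportions are
#' returned unrounded; the convention for display is the nearest 0.1
#' percent.
#'
#' @param r a \code{\link{run_simulation}} result.
#' @return Data frame: \code{ym}, \code{year}, \code{month}, then one
#'   proportion column per category.
#' @export
method_mix_series <- function(r) {
  s <- r$series
  out <- s[, c("ym", "year", "month")]
  for (m in CP_METHODS) out[[m]] <- s[[m]] / s$women_1549
  out
}

#' Proportion of women becoming pregnant per year
#'
#' For each calendar year, the number of women with a pregnancy begun that
#' year divided by the mean number of women 15-49 over the year.
#'
#' @param r a \code{\link{run_simulation}} result.
#' @return Data frame: \code{year}, \code{value}.
#' @export
pregnancy_proportion_series <- function(r) {
  s <- r$series
  data.frame(year = sort(unique(s$year)),
             value = as.numeric(tapply(s$conceptions, s$year, sum) /
                                  tapply(s$women_1549, s$year, mean)))
}

#' Dependency ratio
#'
#' Dependents (children aged 0-14 plus adults aged 65 and over) per adult
#' aged 15-64.
#'
#' @param pop_by_age counts per single year of age; a named vector (names =
#'   ages) or an unnamed vector starting at age 0.
#' @return The ratio.
#' @export
#' @examples
#' dependency_ratio(table(c(5, 15, 40, 70)))  # 1
dependency_ratio <- function(pop_by_age) {
  ages <- if (!is.null(names(pop_by_age))) as.integer(names(pop_by_age)) else
    seq_along(pop_by_age) - 1L
  x <- as.numeric(pop_by_age)
  adults <- sum(x[ages >= 15 & ages <= 64])
  if (adults == 0) stop("no adults aged 15-64: dependency ratio undefined")
  sum(x[ages <= 14 | ages >= 65]) / adults
}

#' Dependency-ratio series from a simulation
#'
#' @param r a \code{\link{run_simulation}} result (uses the stored mid-year
#'   population snapshots).
#' @return Data frame: \code{year}, \code{value}.
#' @export
dependency_ratio_series <- function(r) {
  years <- as.integer(names(r$pyramids))
  data.frame(year = years,
             value = vapply(r$pyramids,
                            function(t) dependency_ratio(colSums(t)),
                            numeric(1)))
}

#' Population pyramid
#'
#' Mid-year population counts by sex and 5-year age group, scaled to the
#' national population when the run was configured with a scale target.
#'
#' @param r a \code{\link{run_simulation}} result.
#' @param year calendar year (must have a mid-year snapshot).
#' @return Matrix: rows \code{F}/\code{M}, columns 5-year age groups.
#' @export
population_pyramid <- function(r, year) {
  t <- r$pyramids[[as.character(year)]]
  if (is.null(t)) stop("no mid-year snapshot for ", year)
  ages <- as.integer(colnames(t))
  grp <- pmin(ages %/% 5L, 17L)
  labs <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
  out <- t(apply(t, 1, function(x) tapply(x, grp, sum)))
  colnames(out) <- labs[as.integer(colnames(out)) + 1L]
  scale <- if (is.null(r$config$scale_target_population)) 1 else
    r$config$scale_target_population / r$config$n_agents
  out * scale
}

#' Scale a simulated count to the national population
#'
#' @param sim_count count observed in the simulation.
#' @param sim_population simulated population size.
#' @param national_population national population it represents.
#' @return \code{sim_count * national_population / sim_population}
#'   (unrounded; user counts are displayed to the nearest 1,000).
#' @export
scale_to_national <- function(sim_count, sim_population,
                              national_population) {
  if (any(sim_population <= 0)) stop("sim_population must be positive")
  sim_count * national_population / sim_population
}

#' Write the reporting tables of a run as delimited text
#'
#' Emits the figure-facing outputs as tidy CSV files: method mix,
#' pregnancy proportion, annual births, dependency ratio, and mid-year
#' pyramids.
#'
#' @param r a \code{\link{run_simulation}} result.
#' @param dir output directory (created if needed).
#' @param pyramid_years years to write pyramid tables for (default: all
#'   snapshot years).
#' @return The directory, invisibly.
#' @export
write_report <- function(r, dir, pyramid_years = names(r$pyramids)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- method_mix_series(r)
  long <- do.call(rbind, lapply(CP_METHODS, function(m)
    data.frame(ym = mm$ym, series = m, value = mm[[m]])))
  utils::write.csv(long, file.path(dir, "methodmix.csv"), row.names = FALSE)
  utils::write.csv(pregnancy_proportion_series(r),
                   file.path(dir, "pregnancy.csv"), row.names = FALSE)
  s <- r$series
  utils::write.csv(data.frame(year = sort(unique(s$year)),
                              births = as.numeric(tapply(s$births, s$year, sum))),
                   file.path(dir, "births.csv"), row.names = FALSE)
  utils::write.csv(dependency_ratio_series(r),
                   file.path(dir, "dependency.csv"), row.names = FALSE)
  for (y in pyramid_years) {
    pyr <- population_pyramid(r, y)
    utils::write.csv(data.frame(age_group = colnames(pyr), t(pyr)),
                     file.path(dir, paste0("pyramid_", y, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
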