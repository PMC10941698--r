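#' Simulated population container
#'
#' A population is a data frame of persons plus the current calendar month.
#' Each person carries the demographic and contraception state the monthly
#' engine needs: identifier, sex, date of birth, vital status, HIV status,
#' current contraceptive method, pregnancy flag and date of last conception,
#' whether that pregnancy was unintended, the date of the last
#' family-planning appointment, and a transient postpartum marker (the month
#' after a pregnancy ends, when after-birth initiation applies).
#'
#' Only women aged 15-49 hold contraception state; men and women outside the
#' reproductive window are always \code{not_using}. Men are carried for
#' population-level outputs (dependency ratio, population-scaled costs).
#'
#' @name cp_population
NULL

cp_new_persons <- function(id, sex, dob, hiv = FALSE, method = 1L) {
  n <- length(id)
  data.frame(id = as.integer(id), sex = as.character(sex),
             dob = as.integer(dob),
             alive = rep(TRUE, n), hiv = rep_len(hiv, n),
             method = rep_len(as.integer(method), n),
             pregnant = rep(FALSE, n), preg_start = rep(NA_integer_, n),
             unintended = rep(FALSE, n), last_appt = rep(NA_integer_, n),
             pp_month = rep(NA_integer_, n), stringsAsFactors = FALSE)
}

cp_population <- function(persons, date) {
  structure(list(persons = persons, date = as.integer(date)),
            class = "cp_population")
}

cp_age_years <- function(pop) (pop$date - pop$persons$dob) %/% 12L

#' Default age structure
#'
#' A young, rapidly growing population: the proportion at age a declines
#' geometrically (about 3 percent per year of age), split evenly by sex --
#' the characteristic profile of a high-fertility population such as
#' Malawi's around 2010.
#'
#' @param max_age oldest single year of age represented.
#' @param decline per-year-of-age proportional decline.
#' @return A data frame with columns \code{sex}, \code{age}, \code{prop}
#'   summing to 1.
#' @export
default_age_structure <- function(max_age = 89, decline = 0.03) {
  ages <- 0:max_age
  w <- exp(-decline * ages)
  w <- w / sum(w) / 2
  data.frame(sex = rep(c("F", "M"), each = length(ages)),
             age = rep(ages, 2), prop = rep(w, 2),
             stringsAsFactors = FALSE)
}

#' Default mortality schedule
#'
#' Annual death probabilities by sex and 5-year age group with the usual
#' shape for a high-mortality setting: elevated early-childhood mortality, a
#' low plateau through adulthood, then roughly exponential increase at older
#' ages; male mortality 15 percent above female.
#'
#' @return A matrix of annual probabilities, rows "0-4" ... "85+", columns
#'   \code{F} and \code{M}, of class \code{cp_mortality}.
#' @export
default_mortality_schedule <- function() {
  qf <- c(0.015, 0.003, 0.002, 0.003, 0.004, 0.005, 0.006, 0.006, 0.007,
          0.008, 0.011, 0.015, 0.022, 0.033, 0.050, 0.080, 0.130, 0.250)
  groups <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
  m <- cbind(F = qf, M = pmin(qf * 1.15, 1))
  rownames(m) <- groups
  class(m) <- c("cp_mortality", class(m))
  m
}

cp_mortality_group <- function(age) pmin(age %/% 5L + 1L, 18L)

#' Initialize a population
#'
#' Draws \code{n} persons from an age-sex structure; women aged 15-49 are
#' assigned a contraceptive method by sampling the baseline method-mix row
#' for their age, and HIV status by the supplied prevalence. Nobody starts
#' pregnant (initial births are handled by
#' \code{\link{schedule_initial_births}}).
#'
#' @param n number of persons.
#' @param age_structure data frame (\code{sex}, \code{age}, \code{prop})
#'   summing to 1; see \code{\link{default_age_structure}}.
#' @param p a \code{\link{cp_parameters}} object.
#' @param hiv_prevalence probability a woman aged 15-49 is HIV positive;
#'   scalar or length-35 vector by single year of age.
#' @param seed integer; the draw is deterministic per seed.
#' @param date starting calendar month (default January of the parameter
#'   baseline year).
#' @return A \code{cp_population} object.
#' @export
initialize_population <- function(n, age_structure = default_age_structure(),
                                  p, hiv_prevalence = 0, seed = 1L,
                                  date = cp_ym(p$baseline_year, 1)) {
  if (n < 0) stop("n must be nonnegative")
  stopifnot(abs(sum(age_structure$prop) - 1) < 1e-6)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L)

  if (n == 0)
    return(cp_population(cp_new_persons(integer(0), character(0), integer(0)),
                         date))
  k <- sample.int(nrow(age_structure), n, replace = TRUE,
                  prob = age_structure$prop)
  sex <- age_structure$sex[k]
  age <- age_structure$age[k]
  dob <- date - age * 12L - sample.int(12L, n, replace = TRUE) + 1L

  persons <- cp_new_persons(seq_len(n), sex, dob)
  wra <- which(sex == "F" & age >= 15 & age <= 49)
  if (length(wra)) {
    hp <- if (length(hiv_prevalence) == 1) rep(hiv_prevalence, 35) else
      hiv_prevalence
    stopifnot(length(hp) == 35)
    persons$hiv[wra] <- stats::runif(length(wra)) < hp[age[wra] - 14L]
    for (a in 15:49) {
      i <- wra[age[wra] == a]
      if (length(i))
        persons$method[i] <- sample.int(11L, length(i), replace = TRUE,
                                        prob = p$method_use_in_2010[a - 14L, ])
    }
  }
  cp_population(persons, date)
}

#' Schedule births for the first nine months
#'
#' At the start of a simulation no woman is pregnant, so no birth could
#' otherwise occur for nine months. Each woman aged 15-49 is therefore
#' assigned a birth event with monthly probability ASFR(age group)/12 over a
#' nine-month window, the birth month drawn uniformly from months 1-9; the
#' woman is marked pregnant with her conception date backdated so the
#' engine's usual nine-month resolution lands on the scheduled month. Her
#' method is set to \code{not_using} for the pregnancy, per the engine's
#' pregnancy convention.
#'
#' @param pop a \code{cp_population} at the simulation start.
#' @param p a \code{\link{cp_parameters}} object.
#' @param seed integer; deterministic per seed.
#' @return A list: \code{population} (updated) and \code{events}, a data
#'   frame with \code{person_id} and \code{birth_ym}.
#' @export
schedule_initial_births <- function(pop, p, seed = 1L) {
  stopifnot(inherits(pop, "cp_population"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L + 1L)

  per <- pop$persons
  age <- cp_age_years(pop)
  wra <- which(per$sex == "F" & age >= 15 & age <= 49 & per$alive)
  if (!length(wra))
    return(list(population = pop,
                events = data.frame(person_id = integer(0),
                                    birth_ym = integer(0))))
  asfr <- p$age_specific_fertility_rates[cp_age_group(age[wra])]
  assigned <- stats::runif(length(wra)) < pmin(asfr / 12 * 9, 1)
  i <- wra[assigned]
  k <- sample.int(9L, length(i), replace = TRUE)  # birth in month start+k-1
  per$pregnant[i] <- TRUE
  per$preg_start[i] <- pop$date + k - 10L
  per$method[i] <- 1L
  per$unintended[i] <- FALSE
  pop$persons <- per
  list(population = pop,
       events = data.frame(person_id = per$id[i],
                           birth_ym = pop$date + k - 1L))
}

#' Apply one month of mortality
#'
#' Each alive person dies this month with probability
#' \code{1 - (1 - q)^(1/12)} where \code{q} is the annual death probability
#' for their sex and 5-year age group. Dead persons take no further
#' transitions.
#'
#' @param pop a \code{cp_population}.
#' @param sched mortality schedule from
#'   \code{\link{default_mortality_schedule}} (or same shape).
#' @param u optional uniform draws indexed like \code{pop$persons} rows (for
#'   common-random-number use); drawn internally if omitted.
#' @param seed seed used when \code{u} is omitted.
#' @return A list: \code{population}, \code{deaths} (count), \code{died}
#'   (person ids).
#' @export
apply_mortality <- function(pop, sched, u = NULL, seed = 1L) {
  per <- pop$persons
  alive <- which(per$alive)
  if (!length(alive)) return(list(population = pop, deaths = 0L,
                                  died = integer(0)))
  age <- (pop$date - per$dob[alive]) %/% 12L
  g <- cp_mortality_group(age)
  if (max(g) > nrow(sched))
    stop("mortality schedule lacks stratum for age group index ", max(g))
  q_ann <- sched[cbind(g, match(per$sex[alive], colnames(sched)))]
  if (any(is.na(q_ann)))
    stop("mortality schedule lacks stratum for sex ",
         paste(unique(per$sex[alive][is.na(q_ann)]), collapse = ","))
  q_m <- 1 - (1 - q_ann)^(1 / 12)
  if (is.null(u)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed) %% 2147483647L + 2L)
    uu <- stats::runif(length(alive))
  } else uu <- u[alive]
  dead <- alive[uu < q_m]
  per$alive[dead] <- FALSE
  per$pregnant[dead] <- FALSE
  per$pp_month[dead] <- NA_integer_
  pop$persons <- per
  list(population = pop, deaths = length(dead), died = per$id[dead])
}

#' Advance the population one calendar month
#'
#' Increments the current date; ages are always derived from date of birth,
#' so no stored age is updated. Women who have crossed age 50 leave the
#' contraception risk set: their method is forced to \code{not_using} and
#' they take no further contraception transitions.
#'
#' @param pop a \code{cp_population}.
#' @return The updated \code{cp_population}.
#' @export
advance_age <- function(pop) {
  pop$date <- pop$date + 1L
  age <- cp_age_years(pop)
  out <- which(pop$persons$sex == "F" & age >= 50 & pop$persons$method != 1L)
  if (length(out)) pop$persons$method[out] <- 1L
  pop
}

#' @export
print.cp_population <- function(x, ...) {
  age <- cp_age_years(x)
  alive <- x$persons$alive
  cat("Population at ", cp_ym_year(x$date), "-", sprintf("%02d", cp_ym_month(x$date)),
      ": ", sum(alive), " alive (", sum(alive & x$persons$sex == "F"),
      " F / ", sum(alive & x$persons$sex == "M"), " M), ",
      sum(alive & x$persons$sex == "F" & age >= 15 & age <= 49),
      " women 15-49, ", sum(x$persons$pregnant[alive]), " pregnant\n", sep = "")
  invisible(x)
}
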