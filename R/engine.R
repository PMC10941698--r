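#' Monthly pregnancy risk while not using contraception
#'
#' The baseline monthly probability for the woman's single year of age,
#' multiplied by the HIV fertility multiplier for her 5-year age group if she
#' is HIV positive, and by the calibrated age-group scaling factor; capped at
#' 1.
#'
#' @param age age in completed years, 15-49 (vectorized).
#' @param hiv_positive logical (vectorized).
#' @param p a \code{\link{cp_parameters}} object.
#' @return Monthly probability of becoming pregnant.
#' @export
#' @examples
#' p <- generate_default_parameters(1)
#' monthly_pregnancy_risk_not_using(17, FALSE, p)
monthly_pregnancy_risk_not_using <- function(age, hiv_positive, p) {
  if (any(age < 15 | age > 49)) stop("age must be within 15-49")
  g <- cp_age_group(age)
  base <- p$pregnancy_not_using_in_2010[age - 14L]
  hiv_mult <- ifelse(hiv_positive, p$pregnancy_not_using_hiv_effect[g], 1)
  pmin(base * hiv_mult * p$scaling_factor_on_monthly_risk_of_pregnancy[g], 1)
}

#' Monthly contraceptive failure risk
#'
#' The method's monthly failure probability, multiplied by the under-25
#' failure risk ratio where applicable and by the age-group scaling factor;
#' capped at 1.
#'
#' @param method method label(s), any category except \code{not_using}.
#' @param age age in completed years, 15-49 (vectorized).
#' @param p a \code{\link{cp_parameters}} object.
#' @return Monthly probability of becoming pregnant while using the method.
#' @export
monthly_failure_risk <- function(method, age, p) {
  if (any(method == "not_using"))
    stop("failure risk is undefined for not_using; ",
         "use monthly_pregnancy_risk_not_using()")
  if (any(!method %in% CP_USE)) stop("unknown method")
  if (any(age < 15 | age > 49)) stop("age must be within 15-49")
  g <- cp_age_group(age)
  rr <- ifelse(age < 25, p$rr_fail_under25, 1)
  pmin(p$failure_by_method[method] * rr *
         p$scaling_factor_on_monthly_risk_of_pregnancy[g], 1)
}

#' Per-method monthly initiation probabilities for non-users
#'
#' The method-and-age initiation table row, times the age-effect multiplier
#' \code{1 + initiation_by_age(age)}, times the Pop intervention multiplier
#' (if an intervention is active at \code{month}), times the secular trend
#' \code{time_age_trend_in_initiation^(years since baseline)}.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @param age ages 15-49 (vectorized).
#' @param month calendar month as \code{cp_ym(year, month)}; defaults to the
#'   baseline date (no trend).
#' @param iv optional \code{\link{cp_intervention}}.
#' @return A matrix (one row per age supplied, columns the 10 methods).
#' @export
initiation_probabilities <- function(p, age, month = cp_ym(p$baseline_year),
                                     iv = NULL) {
  if (any(age < 15 | age > 49)) stop("age must be within 15-49")
  t_yr <- (month - cp_ym(p$baseline_year)) / 12
  mult <- cp_iv_pop(iv, month) * p$time_age_trend_in_initiation^t_yr
  I <- p$initiation_by_method[age - 14L, , drop = FALSE] *
    (1 + p$initiation_by_age[age - 14L])
  I * rep(mult, each = nrow(I))
}

#' Postpartum initiation probabilities
#'
#' The after-birth initiation probabilities, times the PPFP intervention
#' multiplier if active at \code{month}. If the probabilities sum to more
#' than 1 they are rescaled proportionally to sum to 1 (attribute
#' \code{rescaled} is set).
#'
#' @inheritParams initiation_probabilities
#' @return A named length-10 probability vector.
#' @export
postpartum_probabilities <- function(p, month = cp_ym(p$baseline_year),
                                     iv = NULL) {
  pr <- p$initiation_after_birth * cp_iv_ppfp(iv, month)
  resc <- FALSE
  if (sum(pr) > 1) { pr <- pr / sum(pr); resc <- TRUE }
  attr(pr, "rescaled") <- resc
  pr
}

#' One-month outcome for women not using contraception
#'
#' Draws one exclusive outcome per woman from \{pregnancy, initiation of one
#' of the 10 methods, stay\}: pregnancy with
#' \code{\link{monthly_pregnancy_risk_not_using}}, initiation with
#' \code{\link{initiation_probabilities}}. If the non-stay probabilities sum
#' beyond 1 they are rescaled proportionally (the count of affected women is
#' returned in the \code{rescaled} attribute).
#'
#' @param women data frame with columns \code{age} (15-49) and \code{hiv}
#'   (logical); one row per woman.
#' @param p a \code{\link{cp_parameters}} object.
#' @param iv optional \code{\link{cp_intervention}}.
#' @param month calendar month (\code{cp_ym}).
#' @param u optional uniform draws, one per woman (common random numbers);
#'   drawn internally if omitted.
#' @return Data frame with \code{kind} (\code{"pregnancy"},
#'   \code{"initiate"}, \code{"stay"}) and \code{to} (method label or
#'   \code{NA}); attribute \code{rescaled}.
#' @export
step_not_using <- function(women, p, iv = NULL,
                           month = cp_ym(p$baseline_year), u = NULL) {
  n <- nrow(women)
  if (n == 0)
    return(structure(data.frame(kind = character(0), to = character(0)),
                     rescaled = 0L))
  p_preg <- monthly_pregnancy_risk_not_using(women$age, women$hiv, p)
  I <- initiation_probabilities(p, women$age, month, iv)
  tot <- p_preg + rowSums(I)
  over <- tot > 1
  if (any(over)) {
    sc <- ifelse(over, 1 / tot, 1)
    p_preg <- p_preg * sc
    I <- I * sc
  }
  if (is.null(u)) u <- stats::runif(n)
  kind <- rep("stay", n)
  to <- rep(NA_character_, n)
  acc <- p_preg
  kind[u < acc] <- "pregnancy"
  for (j in seq_len(10)) {
    hit <- kind == "stay" & u < acc + I[, j]
    kind[hit] <- "initiate"
    to[hit] <- CP_USE[j]
    acc <- acc + I[, j]
  }
  # women at/after the cumulative mass stay; ensure initiates don't leak
  structure(data.frame(kind = kind, to = to, stringsAsFactors = FALSE),
            rescaled = sum(over))
}

#' One-month outcome for women using a method
#'
#' Sequential exclusive draws: (1) method failure (pregnancy) with
#' \code{\link{monthly_failure_risk}}; otherwise (2) discontinuation with
#' the method's monthly probability times the age-effect multiplier and the
#' stopping trend; otherwise (3) switching with the method's switch-from
#' probability, the destination drawn from the switch-matrix row; otherwise
#' stay. Female sterilization is absorbing: it never discontinues or
#' switches, and can only fail if its failure probability is nonzero.
#'
#' @param women data frame with columns \code{method} (label, not
#'   \code{not_using}) and \code{age} (15-49).
#' @param p a \code{\link{cp_parameters}} object.
#' @param month calendar month (\code{cp_ym}).
#' @param u optional n x 4 matrix of uniforms (failure, discontinuation,
#'   switch, destination); drawn internally if omitted.
#' @return Data frame with \code{kind} (\code{"failure_pregnancy"},
#'   \code{"discontinue"}, \code{"switch"}, \code{"stay"}) and \code{to}
#'   (destination method for switches).
#' @export
step_using <- function(women, p, month = cp_ym(p$baseline_year), u = NULL) {
  n <- nrow(women)
  if (n == 0)
    return(data.frame(kind = character(0), to = character(0)))
  m <- women$method
  age <- women$age
  f <- monthly_failure_risk(m, age, p)
  t_yr <- (month - cp_ym(p$baseline_year)) / 12
  d <- pmin(p$discontinuation_by_method[m] *
              (1 + p$discontinuation_by_age[age - 14L]) *
              p$time_age_trend_in_stopping^t_yr, 1)
  s <- p$prob_switch_from[m]
  ster <- m == "female_sterilization"
  d[ster] <- 0
  s[ster] <- 0
  if (is.null(u)) u <- matrix(stats::runif(4 * n), n, 4)
  kind <- rep("stay", n)
  to <- rep(NA_character_, n)
  kind[u[, 1] < f] <- "failure_pregnancy"
  free <- kind == "stay"
  kind[free & u[, 2] < d] <- "discontinue"
  free <- kind == "stay"
  sw <- free & u[, 3] < s
  kind[sw] <- "switch"
  if (any(sw)) {
    W <- p$switch_matrix[m[sw], , drop = FALSE]
    acc <- numeric(sum(sw))
    dest <- rep(10L, sum(sw))  # fall through to last column on rounding
    left <- rep(TRUE, sum(sw))
    for (j in seq_len(10)) {
      acc <- acc + W[, j]
      hit <- left & u[sw, 4] < acc
      dest[hit] <- j
      left <- left & !hit
    }
    to[sw] <- CP_USE[dest]
  }
  data.frame(kind = kind, to = to, stringsAsFactors = FALSE)
}

#' Resolve pregnancies due this month
#'
#' A pregnancy is resolved exactly nine calendar months after conception:
#' with probability \code{live_birth_probability} a newborn is added (sex
#' drawn 50/50), otherwise the pregnancy ends without a live birth. Either
#' way the woman stops being pregnant and becomes eligible for postpartum
#' initiation in the following month.
#'
#' @param women data frame of pregnant women with column \code{preg_start}
#'   (conception month).
#' @param p a \code{\link{cp_parameters}} object.
#' @param month current calendar month; must equal \code{preg_start + 9} for
#'   every row.
#' @param u optional n x 2 matrix of uniforms (live birth, newborn sex).
#' @return Data frame with \code{kind} (\code{"birth"} or
#'   \code{"pregnancy_end"}) and \code{newborn_sex} (\code{"F"}/\code{"M"},
#'   \code{NA} when no live birth).
#' @export
resolve_pregnancy <- function(women, p, month, u = NULL) {
  n <- nrow(women)
  if (n == 0)
    return(data.frame(kind = character(0), newborn_sex = character(0)))
  if (any(women$preg_start + 9L != month))
    stop("resolve_pregnancy called off-schedule: month must be ",
         "conception month + 9")
  if (is.null(u)) u <- matrix(stats::runif(2 * n), n, 2)
  live <- u[, 1] < p$live_birth_probability
  data.frame(kind = ifelse(live, "birth", "pregnancy_end"),
             newborn_sex = ifelse(live, ifelse(u[, 2] < 0.5, "F", "M"),
                                  NA_character_),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_agents number of persons in the simulated population.
#' @param start_year,end_year simulated calendar span (inclusive; months are
#'   January \code{start_year} through December \code{end_year}).
#' @param seed integer master seed; every stochastic component derives its
#'   draws from it, so identical seeds give identical runs.
#' @param intervention optional \code{\link{cp_intervention}}.
#' @param scale_target_population optional national population count that the
#'   initial simulated population represents; reported user counts and costs
#'   are scaled by \code{scale_target_population / n_agents}.
#' @param age_structure initial age-sex structure
#'   (\code{\link{default_age_structure}}).
#' @param hiv_prevalence HIV prevalence among women 15-49 (scalar or by
#'   single year of age).
#' @return An object of class \code{cp_config}.
#' @export
cp_config <- function(n_agents, start_year = 2010, end_year = 2050,
                      seed = 1L, intervention = NULL,
                      scale_target_population = NULL,
                      age_structure = default_age_structure(),
                      hiv_prevalence = 0.1) {
  if (n_agents <= 0) stop("n_agents must be positive")
  if (start_year >= end_year) stop("start_year must precede end_year")
  if (!is.null(intervention) && !inherits(intervention, "cp_intervention"))
    stop("intervention must be a cp_intervention")
  structure(list(n_agents = as.integer(n_agents),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 seed = as.integer(seed),
                 intervention = intervention,
                 scale_target_population = scale_target_population,
                 age_structure = age_structure,
                 hiv_prevalence = hiv_prevalence),
            class = "cp_config")
}

#' Run the contraception and pregnancy microsimulation
#'
#' Executes the monthly loop over the configured span: aging (women crossing
#' 50 leave the contraception risk set), mortality from the schedule,
#' resolution of pregnancies due (conception + 9 months), postpartum
#' initiation for women whose pregnancy ended the previous month, then one
#' exclusive transition per eligible woman (\code{\link{step_not_using}} or
#' \code{\link{step_using}}), and finally maintenance family-planning
#' appointments at method-specific intervals. Intervention multipliers apply
#' from their start date onward.
#'
#' All randomness derives from \code{config$seed} through per-month,
#' per-purpose substreams indexed by person id, so two runs with the same
#' seed but different interventions share random numbers person by person
#' (common random numbers), and identical configurations reproduce the event
#' log exactly.
#'
#' @param config a \code{\link{cp_config}}.
#' @param p a \code{\link{cp_parameters}} object (validated before any
#'   stepping).
#' @param sched mortality schedule (\code{\link{default_mortality_schedule}}).
#' @return An object of class \code{cp_sim}: list with \code{series} (one
#'   row per month: state counts among women 15-49, pregnancies begun,
#'   births, deaths, population sizes), \code{events} (the event log: month,
#'   person id, kind, from, to, detail), \code{pyramids} (mid-year age-sex
#'   count matrices by year), \code{population} (final state),
#'   \code{initial} (state after initial birth scheduling), \code{config},
#'   and \code{rescaled_months} (months in which outcome probabilities had
#'   to be proportionally rescaled).
#' @export
run_simulation <- function(config, p, sched = default_mortality_schedule()) {
  stopifnot(inherits(config, "cp_config"), inherits(p, "cp_parameters"))
  val <- validate_parameters(p)
  if (!val$ok) stop("invalid parameter set; see validate_parameters()")

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  seed <- config$seed
  iv <- config$intervention
  pop <- initialize_population(config$n_agents, config$age_structure, p,
                               config$hiv_prevalence, seed = seed,
                               date = cp_ym(config$start_year, 1))
  sb <- schedule_initial_births(pop, p, seed = seed)
  pop <- sb$population
  per <- pop$persons
  initial <- per

  start_ym <- cp_ym(config$start_year, 1)
  end_ym <- cp_ym(config$end_year, 12)
  months <- start_ym:end_ym
  nm <- length(months)

  series <- matrix(0L, nm, 20)
  colnames(series) <- c("ym", "women_1549", CP_METHODS, "pregnant",
                        "conceptions", "births", "deaths", "pop_total",
                        "n_15_49", "pop_f")
  pyramids <- list()
  maint <- p$days_between_appts_for_maintenance
  maint_idx <- match(names(maint), CP_METHODS)
  rescaled_months <- 0L

  ev <- vector("list", 4096); ev_n <- 0L
  log_ev <- function(month, id, kind, from = NA_integer_, to = NA_character_,
                     detail = NA_integer_) {
    if (!length(id)) return()
    ev_n <<- ev_n + 1L
    if (ev_n > length(ev)) length(ev) <<- 2L * ev_n
    ev[[ev_n]] <<- list(month = rep.int(month, length(id)), id = id,
                        kind = rep.int(kind, length(id)),
                        from = if (length(from) == 1L) rep(from, length(id)) else from,
                        to = if (length(to) == 1L) rep(to, length(id)) else to,
                        detail = if (length(detail) == 1L) rep(detail, length(id)) else detail)
  }

  for (mi in seq_len(nm)) {
    ym <- months[mi]
    if (mi > 1L) {
      pop$date <- ym
      age_all <- (ym - per$dob) %/% 12L
      ex <- which(per$alive & per$sex == "F" & age_all >= 50L & per$method != 1L)
      if (length(ex)) {
        log_ev(ym, per$id[ex], "age_exit", from = per$method[ex])
        per$method[ex] <- 1L
      }
    } else age_all <- (ym - per$dob) %/% 12L

    # --- mortality -------------------------------------------------------
    u_mort <- cp_runif(seed, ym, 1L, per$id)
    alive_i <- which(per$alive)
    g <- cp_mortality_group(age_all[alive_i])
    q_ann <- sched[cbind(g, match(per$sex[alive_i], colnames(sched)))]
    dead <- alive_i[u_mort[alive_i] < 1 - (1 - q_ann)^(1 / 12)]
    if (length(dead)) {
      per$alive[dead] <- FALSE
      per$pregnant[dead] <- FALSE
      per$pp_month[dead] <- NA_integer_
      log_ev(ym, per$id[dead], "death")
    }
    n_deaths <- length(dead)

    # --- pregnancy resolutions due this month ---------------------------
    due <- which(per$alive & per$pregnant & per$preg_start + 9L == ym)
    n_births <- 0L
    if (length(due)) {
      u_res <- cbind(cp_runif(seed, ym, 2L, per$id[due]),
                     cp_runif(seed, ym, 3L, per$id[due]))
      res <- resolve_pregnancy(per[due, c("id", "preg_start")], p, ym, u = u_res)
      live <- res$kind == "birth"
      n_births <- sum(live)
      per$pregnant[due] <- FALSE
      per$pp_month[due] <- ym
      if (n_births) {
        nb_id <- max(per$id) + seq_len(n_births)
        nb <- cp_new_persons(nb_id, res$newborn_sex[live], rep(ym, n_births))
        per <- rbind(per, nb)
        age_all <- c(age_all, rep(0L, n_births))
        log_ev(ym, per$id[due[live]], "birth", to = res$newborn_sex[live],
               detail = nb_id)
      }
      if (any(!live)) log_ev(ym, per$id[due[!live]], "pregnancy_end")
    }

    eligible <- per$alive & per$sex == "F" & age_all >= 15L & age_all <= 49L

    # --- postpartum initiation (pregnancy ended last month) -------------
    pp <- which(eligible & !is.na(per$pp_month) & per$pp_month == ym - 1L)
    if (length(pp)) {
      pr <- postpartum_probabilities(p, ym, iv)
      u_pp <- cp_runif(seed, ym, 4L, per$id[pp])
      dest <- rep(0L, length(pp))
      acc <- 0
      left <- rep(TRUE, length(pp))
      for (j in seq_len(10)) {
        acc <- acc + pr[j]
        hit <- left & u_pp < acc
        dest[hit] <- j
        left <- left & !hit
      }
      init <- dest > 0L
      if (any(init)) {
        per$method[pp[init]] <- dest[init] + 1L
        per$last_appt[pp[init]] <- ym
        log_ev(ym, per$id[pp[init]], "postpartum_initiate",
               to = CP_USE[dest[init]])
        log_ev(ym, per$id[pp[init]], "initiation_appt",
               to = CP_USE[dest[init]])
      }
    }
    per$pp_month[!is.na(per$pp_month) & per$pp_month <= ym - 1L] <- NA_integer_

    handled <- rep(FALSE, nrow(per))
    handled[pp] <- TRUE

    # --- transitions: not using -----------------------------------------
    nu <- which(eligible & !per$pregnant & !handled & per$method == 1L)
    n_conceptions <- 0L
    if (length(nu)) {
      out <- step_not_using(
        data.frame(age = age_all[nu], hiv = per$hiv[nu]),
        p, iv, ym, u = cp_runif(seed, ym, 5L, per$id[nu]))
      if (attr(out, "rescaled") > 0) rescaled_months <- rescaled_months + 1L
      cv <- out$kind == "pregnancy"
      if (any(cv)) {
        i <- nu[cv]
        per$pregnant[i] <- TRUE
        per$preg_start[i] <- ym
        per$unintended[i] <- FALSE
        n_conceptions <- n_conceptions + length(i)
        log_ev(ym, per$id[i], "pregnancy")
      }
      ini <- out$kind == "initiate"
      if (any(ini)) {
        i <- nu[ini]
        m_new <- match(out$to[ini], CP_METHODS)
        per$method[i] <- m_new
        per$last_appt[i] <- ym
        log_ev(ym, per$id[i], "initiate", to = out$to[ini])
        log_ev(ym, per$id[i], "initiation_appt", to = out$to[ini])
      }
    }

    # --- transitions: using ---------------------------------------------
    us <- which(eligible & !per$pregnant & !handled & per$method != 1L)
    if (length(us)) {
      u4 <- cbind(cp_runif(seed, ym, 6L, per$id[us]),
                  cp_runif(seed, ym, 7L, per$id[us]),
                  cp_runif(seed, ym, 8L, per$id[us]),
                  cp_runif(seed, ym, 9L, per$id[us]))
      out <- step_using(
        data.frame(method = CP_METHODS[per$method[us]], age = age_all[us],
                   stringsAsFactors = FALSE),
        p, ym, u = u4)
      fl <- out$kind == "failure_pregnancy"
      if (any(fl)) {
        i <- us[fl]
        log_ev(ym, per$id[i], "failure_pregnancy", from = per$method[i])
        per$pregnant[i] <- TRUE
        per$preg_start[i] <- ym
        per$unintended[i] <- TRUE
        per$method[i] <- 1L
        n_conceptions <- n_conceptions + length(i)
      }
      dc <- out$kind == "discontinue"
      if (any(dc)) {
        i <- us[dc]
        log_ev(ym, per$id[i], "discontinue", from = per$method[i])
        per$method[i] <- 1L
      }
      sw <- out$kind == "switch"
      if (any(sw)) {
        i <- us[sw]
        m_new <- match(out$to[sw], CP_METHODS)
        log_ev(ym, per$id[i], "switch", from = per$method[i], to = out$to[sw])
        per$method[i] <- m_new
        per$last_appt[i] <- ym
        log_ev(ym, per$id[i], "initiation_appt", to = out$to[sw])
      }
    }

    # --- maintenance appointments ---------------------------------------
    mu <- which(eligible & !per$pregnant & per$method %in% maint_idx)
    if (length(mu)) {
      m_lab <- CP_METHODS[per$method[mu]]
      elapsed <- (ym - per$last_appt[mu]) * CP_DAYS_PER_MONTH
      first <- is.na(per$last_appt[mu])
      due_m <- first | elapsed > maint[m_lab]
      if (any(due_m)) {
        i <- mu[due_m]
        per$last_appt[i] <- ym
        log_ev(ym, per$id[i][first[due_m]], "initiation_appt",
               to = m_lab[due_m][first[due_m]])
        log_ev(ym, per$id[i][!first[due_m]], "maintenance_appt",
               to = m_lab[due_m][!first[due_m]])
      }
    }

    # --- monthly series --------------------------------------------------
    w49 <- eligible
    series[mi, ] <- c(ym, sum(w49),
                      tabulate(per$method[w49], 11L),
                      sum(per$pregnant[w49]), n_conceptions, n_births,
                      n_deaths, sum(per$alive),
                      sum(per$alive & age_all >= 15L & age_all <= 49L),
                      sum(per$alive & per$sex == "F"))

    if (cp_ym_month(ym) == 6L) {
      a <- age_all[per$alive]
      s <- per$sex[per$alive]
      pyramids[[as.character(cp_ym_year(ym))]] <-
        table(factor(s, c("F", "M")), factor(pmin(a, 100L), 0:100))
    }
    pop$persons <- per
  }

  events <- if (ev_n) {
    ee <- ev[seq_len(ev_n)]
    data.frame(month = unlist(lapply(ee, `[[`, "month")),
               person_id = unlist(lapply(ee, `[[`, "id")),
               kind = unlist(lapply(ee, `[[`, "kind")),
               from = CP_METHODS[unlist(lapply(ee, `[[`, "from"))],
               to = unlist(lapply(ee, `[[`, "to")),
               detail = unlist(lapply(ee, `[[`, "detail")),
               stringsAsFactors = FALSE)
  } else data.frame(month = integer(0), person_id = integer(0),
                    kind = character(0), from = character(0),
                    to = character(0), detail = integer(0))
  events <- events[order(events$month), ]
  rownames(events) <- NULL

  df <- as.data.frame(series)
  df$year <- cp_ym_year(df$ym)
  df$month <- cp_ym_month(df$ym)

  structure(list(series = df, events = events, pyramids = pyramids,
                 population = pop, initial = initial, config = config,
                 rescaled_months = rescaled_months),
            class = "cp_sim")
}
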