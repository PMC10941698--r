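#' Contraceptive calendar state codes
#'
#' Month-by-month calendars use one character per month, in the style of
#' survey contraceptive calendars: \code{"0"} not using, \code{"1"}-\code{"9"}
#' the first nine methods (pill through withdrawal), \code{"T"} other
#' traditional, \code{"*"} pregnant, \code{"B"} pregnancy ending in a live
#' birth, \code{"E"} pregnancy ending otherwise. The month after a
#' \code{"B"}/\code{"E"} code shows the postpartum outcome (a method, or
#' \code{"0"}).
#'
#' @return Data frame with columns \code{code} and \code{state}.
#' @export
cp_calendar_codes <- function() {
  data.frame(code = c("0", as.character(1:9), "T", "*", "B", "E"),
             state = c(CP_METHODS, "pregnant", "birth", "pregnancy_end"),
             stringsAsFactors = FALSE)
}

CP_CAL_CODE <- c("0", as.character(1:9), "T")  # index = method index

#' Simulate month-by-month contraceptive calendars
#'
#' Generates retrospective-calendar-style event histories from known
#' transition probabilities, using the same monthly step logic as the
#' simulation engine restricted to contraception and pregnancy states (no
#' mortality, no interventions, probabilities at the baseline date). Each
#' woman's record is a string of state codes (see
#' \code{\link{cp_calendar_codes}}); a pregnancy shows nine \code{"*"}
#' months followed by a \code{"B"} or \code{"E"} code, then the postpartum
#' outcome.
#'
#' @param p a \code{\link{cp_parameters}} object.
#' @param n_women number of women.
#' @param n_months calendar length in months.
#' @param seed integer; deterministic per seed.
#' @param ages ages at the start of the calendar (recycled); default drawn
#'   uniformly from 15-44 so nobody ages out of 15-49 within five years.
#' @return Data frame of class \code{cp_calendars}: \code{woman_id},
#'   \code{age_at_start}, \code{calendar} (one code per month).
#' @export
simulate_calendars <- function(p, n_women, n_months, seed = 1L,
                               ages = NULL) {
  stopifnot(n_months >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L)
  out <- data.frame(woman_id = seq_len(n_women),
                    age_at_start = integer(n_women) + NA_integer_,
                    calendar = character(n_women),
                    stringsAsFactors = FALSE)
  class(out) <- c("cp_calendars", class(out))
  attr(out, "legend") <- cp_calendar_codes()
  if (n_women == 0) return(out)

  age0 <- if (is.null(ages)) sample(15:44, n_women, replace = TRUE) else
    as.integer(rep_len(ages, n_women))
  method <- integer(n_women)
  for (a in unique(age0)) {
    i <- which(age0 == a)
    method[i] <- sample.int(11L, length(i), replace = TRUE,
                            prob = p$method_use_in_2010[a - 14L, ])
  }
  preg_ct <- integer(n_women)   # months since conception (0 = not pregnant)
  pp <- logical(n_women)
  mat <- matrix("0", n_women, n_months)
  base_ym <- cp_ym(p$baseline_year, 1)

  for (t in seq_len(n_months)) {
    age <- pmin(age0 + (t - 1L) %/% 12L, 49L)

    res <- which(preg_ct == 9L)
    if (length(res)) {
      live <- stats::runif(length(res)) < p$live_birth_probability
      mat[res, t] <- ifelse(live, "B", "E")
      preg_ct[res] <- 0L
      pp[res] <- TRUE
      method[res] <- 1L
    }
    cont <- which(preg_ct > 0L)
    if (length(cont)) {
      mat[cont, t] <- "*"
      preg_ct[cont] <- preg_ct[cont] + 1L
    }

    ppw <- which(pp & preg_ct == 0L & !(seq_len(n_women) %in% res))
    if (length(ppw)) {
      pr <- postpartum_probabilities(p, base_ym, NULL)
      u <- stats::runif(length(ppw))
      dest <- rep(0L, length(ppw)); acc <- 0; left <- rep(TRUE, length(ppw))
      for (j in 1:10) {
        acc <- acc + pr[j]
        hit <- left & u < acc
        dest[hit] <- j; left <- left & !hit
      }
      method[ppw] <- dest + 1L
      mat[ppw, t] <- CP_CAL_CODE[method[ppw]]
      pp[ppw] <- FALSE
    }

    active <- preg_ct == 0L & !pp & !(seq_len(n_women) %in% c(res, ppw))
    nu <- which(active & method == 1L)
    if (length(nu)) {
      o <- step_not_using(data.frame(age = age[nu], hiv = FALSE), p,
                          month = base_ym)
      cv <- o$kind == "pregnancy"
      mat[nu[cv], t] <- "*"; preg_ct[nu[cv]] <- 1L
      ini <- o$kind == "initiate"
      method[nu[ini]] <- match(o$to[ini], CP_METHODS)
      mat[nu[ini], t] <- CP_CAL_CODE[method[nu[ini]]]
      # stayers keep "0" (matrix default)
    }
    us <- which(active & method != 1L)
    if (length(us)) {
      o <- step_using(data.frame(method = CP_METHODS[method[us]],
                                 age = age[us], stringsAsFactors = FALSE),
                      p, month = base_ym)
      fl <- o$kind == "failure_pregnancy"
      mat[us[fl], t] <- "*"; preg_ct[us[fl]] <- 1L; method[us[fl]] <- 1L
      dc <- o$kind == "discontinue"
      method[us[dc]] <- 1L  # entry stays "0"
      sw <- o$kind == "switch"
      method[us[sw]] <- match(o$to[sw], CP_METHODS)
      st <- o$kind == "stay"
      keep <- us[sw | st]
      mat[keep, t] <- CP_CAL_CODE[method[keep]]
    }
  }
  out$age_at_start <- age0
  out$calendar <- apply(mat, 1, paste, collapse = "")
  out
}

cp_est <- function(events, exposure) {
  est <- ifelse(exposure > 0, events / exposure, NA_real_)
  data.frame(events = events, exposure = exposure, est = est,
             se = ifelse(exposure > 0, sqrt(pmax(est * (1 - est), 0) /
                                              exposure), NA_real_))
}

#' Occurrence-exposure estimation of monthly transition probabilities
#'
#' Recovers the engine's monthly probabilities from calendars by dividing
#' event counts by person-months at risk, matched to the engine's
#' sequential convention: failure out of all using months; discontinuation
#' out of using months that did not fail; switching out of using months
#' that neither failed nor discontinued; the switch destination matrix from
#' destination counts; initiation (and pregnancy) out of non-using months;
#' after-birth initiation out of postpartum months. Binomial standard
#' errors are attached. A quantity with zero exposure is \code{NA}
#' (undefined), not zero.
#'
#' @param calendars a \code{\link{simulate_calendars}} result (or any data
#'   frame with a \code{calendar} column of code strings).
#' @return An object of class \code{cp_calendar_fit}: per-quantity data
#'   frames (\code{events}, \code{exposure}, \code{est}, \code{se}), the
#'   estimated \code{switch_matrix}, and the total woman-months parsed.
#' @export
estimate_monthly_probabilities <- function(calendars) {
  codes <- strsplit(calendars$calendar, "")
  Tn <- lengths(codes)
  if (any(Tn < 2)) stop("calendars need at least two months")
  prev <- unlist(lapply(codes, function(x) x[-length(x)]))
  nxt <- unlist(lapply(codes, function(x) x[-1]))

  is_method <- nxt %in% CP_CAL_CODE[-1]
  m_next <- match(nxt, CP_CAL_CODE)  # NA unless a method/not_using code

  # --- from not using -------------------------------------------------
  i0 <- prev == "0"
  E0 <- sum(i0)
  conceptions <- sum(i0 & nxt == "*")
  init_ev <- vapply(CP_CAL_CODE[-1], function(cd) sum(i0 & nxt == cd),
                    numeric(1))
  initiation <- cp_est(init_ev, rep(E0, 10))
  pregnancy_nu <- cp_est(conceptions, E0)

  # --- from each method -----------------------------------------------
  fail_ev <- disc_ev <- sw_ev <- Em <- numeric(10)
  swm <- matrix(0, 10, 10, dimnames = list(CP_USE, CP_USE))
  for (j in 1:10) {
    im <- prev == CP_CAL_CODE[j + 1]
    Em[j] <- sum(im)
    fail_ev[j] <- sum(im & nxt == "*")
    disc_ev[j] <- sum(im & nxt == "0")
    sw <- im & is_method & nxt != prev
    sw_ev[j] <- sum(sw)
    if (sw_ev[j] > 0)
      swm[j, ] <- vapply(CP_CAL_CODE[-1], function(cd) sum(sw & nxt == cd),
                         numeric(1)) / sw_ev[j]
    else swm[j, ] <- NA_real_
  }
  failure <- cp_est(fail_ev, Em)
  discontinuation <- cp_est(disc_ev, Em - fail_ev)
  switch_from <- cp_est(sw_ev, Em - fail_ev - disc_ev)
  rownames(failure) <- rownames(discontinuation) <- rownames(switch_from) <-
    CP_USE
  rownames(initiation) <- CP_USE

  # --- postpartum -----------------------------------------------------
  ipp <- prev %in% c("B", "E")
  Epp <- sum(ipp)
  ab_ev <- vapply(CP_CAL_CODE[-1], function(cd) sum(ipp & nxt == cd),
                  numeric(1))
  after_birth <- cp_est(ab_ev, rep(Epp, 10))
  rownames(after_birth) <- CP_USE

  structure(list(initiation_by_method = initiation,
                 pregnancy_not_using = pregnancy_nu,
                 failure_by_method = failure,
                 discontinuation_by_method = discontinuation,
                 prob_switch_from = switch_from,
                 switch_matrix = swm,
                 initiation_after_birth = after_birth,
                 woman_months = length(prev)),
            class = "cp_calendar_fit")
}

#' @export
coef.cp_calendar_fit <- function(object, ...) {
  pick <- function(nm) stats::setNames(object[[nm]]$est,
                                       paste(nm, CP_USE, sep = "."))
  c(pick("initiation_by_method"),
    stats::setNames(object$pregnancy_not_using$est, "pregnancy_not_using"),
    pick("failure_by_method"), pick("discontinuation_by_method"),
    pick("prob_switch_from"), pick("initiation_after_birth"))
}

#' @export
print.cp_calendar_fit <- function(x, ...) {
  cat("Occurrence-exposure estimates from", x$woman_months,
      "woman-month transitions\n")
  for (nm in c("initiation_by_method", "failure_by_method",
               "discontinuation_by_method", "prob_switch_from",
               "initiation_after_birth")) {
    cat("\n", nm, ":\n", sep = "")
    print(round(x[[nm]], 5))
  }
  cat("\npregnancy while not using: est",
      signif(x$pregnancy_not_using$est, 4), "( se",
      signif(x$pregnancy_not_using$se, 3), ")\n")
  invisible(x)
}

#' Write calendars as delimited text
#'
#' One row per woman with the month codes as a single string, plus a legend
#' file mapping codes to states.
#'
#' @param calendars a \code{\link{simulate_calendars}} result.
#' @param path CSV path; the legend is written alongside with suffix
#'   \code{"_legend.csv"}.
#' @return \code{path}, invisibly.
#' @export
write_calendars <- function(calendars, path) {
  utils::write.csv(as.data.frame(calendars), path, row.names = FALSE)
  utils::write.csv(cp_calendar_codes(),
                   sub("\\.csv$", "_legend.csv", path), row.names = FALSE)
  invisible(path)
}
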