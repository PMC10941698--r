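#' @export
print.cp_sim <- function(x, ...) {
  s <- x$series
  cat("Contraception/pregnancy microsimulation\n")
  cat("  span: ", min(s$year), "-", max(s$year), ", agents at start: ",
      x$config$n_agents, ", seed: ", x$config$seed, "\n", sep = "")
  cat("  intervention:",
      if (is.null(x$config$intervention)) "none" else
        paste0("Pop/PPFP from ", cp_ym_year(x$config$intervention$start_ym)),
      "\n")
  cat("  births:", sum(s$births), " deaths:", sum(s$deaths),
      " pregnancies begun:", sum(s$conceptions), "\n")
  cat("  final population:", s$pop_total[nrow(s)], "\n")
  invisible(x)
}

#' @export
summary.cp_sim <- function(object, ...) {
  s <- object$series
  first <- s[1, ]
  last <- s[nrow(s), ]
  mix <- method_mix_series(object)
  out <- list(
    years = range(s$year),
    population = c(start = first$pop_total, end = last$pop_total),
    births = sum(s$births), deaths = sum(s$deaths),
    conceptions = sum(s$conceptions),
    prevalence_start = 1 - mix$not_using[1],
    prevalence_end = 1 - mix$not_using[nrow(mix)],
    final_mix = unlist(mix[nrow(mix), CP_METHODS]))
  class(out) <- "summary.cp_sim"
  out
}

#' @export
print.summary.cp_sim <- function(x, ...) {
  cat("Simulation ", x$years[1], "-", x$years[2], "\n", sep = "")
  cat("  population: ", x$population["start"], " -> ", x$population["end"],
      "\n", sep = "")
  cat("  births: ", x$births, "  deaths: ", x$deaths,
      "  pregnancies begun: ", x$conceptions, "\n", sep = "")
  cat(sprintf("  contraceptive prevalence (women 15-49): %.1f%% -> %.1f%%\n",
              100 * x$prevalence_start, 100 * x$prevalence_end))
  cat("  final method mix (% of women 15-49):\n")
  print(round(100 * x$final_mix, 1))
  invisible(x)
}

#' Plot simulation outputs
#'
#' Base-graphics panels: contraceptive prevalence among women 15-49, annual
#' births, and the method mix over time.
#'
#' @param x a \code{cp_sim} object.
#' @param which subset of \code{c("prevalence", "births", "mix")}.
#' @param ... passed to \code{matplot}/\code{plot}.
#' @export
plot.cp_sim <- function(x, which = c("prevalence", "births", "mix"), ...) {
  s <- x$series
  t <- s$year + (s$month - 0.5) / 12
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if ("prevalence" %in% which) {
    prev <- 1 - s$not_using / s$women_1549
    graphics::plot(t, prev, type = "l", xlab = "year",
                   ylab = "using any method", ylim = c(0, 1),
                   main = "Contraceptive prevalence, women 15-49", ...)
  }
  if ("births" %in% which) {
    by_year <- tapply(s$births, s$year, sum)
    graphics::plot(as.integer(names(by_year)), by_year, type = "h",
                   xlab = "year", ylab = "births", main = "Annual births", ...)
  }
  if ("mix" %in% which) {
    mix <- as.matrix(s[, CP_USE]) / s$women_1549
    graphics::matplot(t, mix, type = "l", lty = 1, col = seq_len(10),
                      xlab = "year", ylab = "proportion of women 15-49",
                      main = "Method mix", ...)
    graphics::legend("topleft", legend = CP_USE, col = seq_len(10), lty = 1,
                     cex = 0.6, bty = "n")
  }
  invisible(x)
}

#' Replay an event log
#'
#' Reconstructs the final person table of a simulation by applying its event
#' log to the recorded initial state. Used to verify that the log is a
#' complete account of every state change.
#'
#' @param sim a \code{cp_sim} object.
#' @return A persons data frame in the same shape as
#'   \code{sim$population$persons}.
#' @export
replay_events <- function(sim) {
  per <- sim$initial
  ev <- sim$events
  if (!nrow(ev)) return(per)
  grp <- cumsum(c(TRUE, ev$kind[-1] != ev$kind[-nrow(ev)] |
                    ev$month[-1] != ev$month[-nrow(ev)]))
  for (ch in split(seq_len(nrow(ev)), grp)) {
    kind <- ev$kind[ch[1]]
    month <- ev$month[ch[1]]
    id <- ev$person_id[ch]
    to <- ev$to[ch]
    i <- match(id, per$id)
    switch(kind,
      death = {
        per$alive[i] <- FALSE
        per$pregnant[i] <- FALSE
      },
      age_exit = { per$method[i] <- 1L },
      birth = {
        per$pregnant[i] <- FALSE
        nb <- cp_new_persons(ev$detail[ch], to, rep(month, length(ch)))
        per <- rbind(per, nb)
      },
      pregnancy_end = { per$pregnant[i] <- FALSE },
      postpartum_initiate = ,
      initiate = {
        per$method[i] <- match(to, CP_METHODS)
        per$last_appt[i] <- month
      },
      pregnancy = {
        per$pregnant[i] <- TRUE
        per$preg_start[i] <- month
      },
      failure_pregnancy = {
        per$pregnant[i] <- TRUE
        per$preg_start[i] <- month
        per$method[i] <- 1L
      },
      discontinue = { per$method[i] <- 1L },
      switch = {
        per$method[i] <- match(to, CP_METHODS)
        per$last_appt[i] <- month
      },
      initiation_appt = ,
      maintenance_appt = { per$last_appt[i] <- month })
  }
  per
}
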