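#' Family-planning scale-up intervention
#'
#' Two interventions are modeled, following a national costed implementation
#' plan: a population-wide demand-creation campaign ("Pop") that multiplies
#' the monthly initiation probability of each modern method, and a postpartum
#' family planning program ("PPFP") that multiplies the probability of
#' starting each modern method in the month after a pregnancy ends.
#' Traditional methods (and non-use) are unaffected: their multiplier is
#' fixed at 1.
#'
#' @param pop named multipliers of \code{initiation_by_method} for modern
#'   methods; a scalar is recycled over all modern methods.
#' @param ppfp named multipliers of \code{initiation_after_birth} for modern
#'   methods; a scalar is recycled.
#' @param start_year,start_month calendar date from which the multipliers
#'   apply (inclusive).
#' @return An object of class \code{cp_intervention} holding full length-10
#'   multiplier vectors (traditional methods at exactly 1).
#' @export
#' @examples
#' cp_intervention(pop = 2, ppfp = 1.5, start_year = 2023)
cp_intervention <- function(pop = 1, ppfp = 1, start_year = 2023,
                            start_month = 1) {
  expand <- function(x, what) {
    out <- stats::setNames(rep(1, 10), CP_USE)
    if (length(x) == 1 && is.null(names(x))) {
      out[CP_MODERN] <- x
    } else {
      if (is.null(names(x)) || !all(names(x) %in% CP_MODERN))
        stop(what, " multipliers must be named after modern methods")
      out[names(x)] <- x
    }
    if (any(out < 0)) stop(what, " multipliers must be >= 0")
    if (any(out[setdiff(CP_USE, CP_MODERN)] != 1))
      stop("traditional methods must keep multiplier 1")
    out
  }
  structure(list(pop = expand(pop, "pop"), ppfp = expand(ppfp, "ppfp"),
                 start_ym = cp_ym(start_year, start_month)),
            class = "cp_intervention")
}

#' @export
print.cp_intervention <- function(x, ...) {
  cat("Intervention from", cp_ym_year(x$start_ym), "\b-\b",
      cp_ym_month(x$start_ym), "\n")
  cat("  Pop multipliers:\n")
  print(round(x$pop[CP_MODERN], 3))
  cat("  PPFP multipliers:\n")
  print(round(x$ppfp[CP_MODERN], 3))
  invisible(x)
}

# multipliers in force at month ym (identity before start)
cp_iv_pop <- function(iv, ym) {
  if (is.null(iv) || ym < iv$start_ym) stats::setNames(rep(1, 10), CP_USE)
  else iv$pop
}

cp_iv_ppfp <- function(iv, ym) {
  if (is.null(iv) || ym < iv$start_ym) stats::setNames(rep(1, 10), CP_USE)
  else iv$ppfp
}
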