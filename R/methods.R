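#' Contraceptive method categories
#'
#' The simulation distinguishes eleven contraception states: \code{not_using}
#' plus ten methods. Modern methods are pill, IUD, injection, implant,
#' male condom, female sterilization and "other modern" (in Malawi essentially
#' the female condom); the remainder (periodic abstinence, withdrawal, other
#' traditional) are traditional methods.
#'
#' @return A data frame with one row per category: \code{label} and
#'   \code{is_modern} (\code{not_using} counts as not modern).
#' @export
#' @examples
#' cp_methods()
cp_methods <- function() {
  data.frame(label = CP_METHODS,
             is_modern = CP_METHODS %in% CP_MODERN,
             stringsAsFactors = FALSE)
}

CP_METHODS <- c("not_using", "pill", "IUD", "injection", "implant",
                "male_condom", "female_sterilization", "other_modern",
                "periodic_abstinence", "withdrawal", "other_traditional")

CP_MODERN <- c("pill", "IUD", "injection", "implant", "male_condom",
               "female_sterilization", "other_modern")

# the ten "using" states (everything except not_using)
CP_USE <- CP_METHODS[-1]

CP_AGES <- 15:49

CP_AGE_GROUPS <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")

# 5-year age group index (1..7) for ages 15-49
cp_age_group <- function(age) {
  stopifnot(all(age >= 15 & age <= 49))
  pmin((age - 15L) %/% 5L + 1L, 7L)
}

# calendar months are integers: ym = year * 12 + (month - 1)
cp_ym <- function(year, month = 1L) as.integer(year) * 12L + as.integer(month) - 1L

cp_ym_year <- function(ym) ym %/% 12L

cp_ym_month <- function(ym) ym %% 12L + 1L

# average days per calendar month (365.25 / 12)
CP_DAYS_PER_MONTH <- 30.4375

# deterministic uniforms for one (seed, month, stream), indexed by person id;
# identical across runs sharing a seed even if their populations diverge,
# which is what makes common-random-number scenario comparisons exact.
cp_runif <- function(seed, ym, stream, ids, n_max = NULL) {
  if (is.null(n_max)) n_max <- if (length(ids)) max(ids) else 0L
  if (n_max == 0L) return(numeric(0))
  s <- (as.numeric(seed) %% 65011) * 33013 + (as.numeric(ym) %% 49999) * 40503 +
    stream * 97
  set.seed(as.integer(s %% 2147483629))
  stats::runif(n_max)[ids]
}
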