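# Controlled parameter sets for oracle tests.

# A fully homogeneous set: no age effects, no under-25 risk ratio, unit
# scaling factors, no trends, a given constant for each probability family.
# The occurrence-exposure estimand then equals the table parameter exactly.
flat_params <- function(preg_nu = 0.015,
                        init = c(pill = 0.003, IUD = 0.0005,
                                 injection = 0.01, implant = 0.002,
                                 male_condom = 0.0025,
                                 female_sterilization = 0.0008,
                                 other_modern = 0.0004,
                                 periodic_abstinence = 0.002,
                                 withdrawal = 0.0015,
                                 other_traditional = 0.0015),
                        fail = c(pill = 0.004, IUD = 0.0006,
                                 injection = 0.002, implant = 0.0003,
                                 male_condom = 0.0085,
                                 female_sterilization = 0,
                                 other_modern = 0.006,
                                 periodic_abstinence = 0.012,
                                 withdrawal = 0.013,
                                 other_traditional = 0.012),
                        disc = c(pill = 0.03, IUD = 0.01, injection = 0.024,
                                 implant = 0.012, male_condom = 0.035,
                                 female_sterilization = 0,
                                 other_modern = 0.03,
                                 periodic_abstinence = 0.03,
                                 withdrawal = 0.034,
                                 other_traditional = 0.03),
                        switch_from = c(pill = 0.02, IUD = 0.006,
                                        injection = 0.015, implant = 0.008,
                                        male_condom = 0.022,
                                        female_sterilization = 0,
                                        other_modern = 0.02,
                                        periodic_abstinence = 0.018,
                                        withdrawal = 0.02,
                                        other_traditional = 0.018),
                        after_birth = c(pill = 0.012, IUD = 0.003,
                                        injection = 0.09, implant = 0.035,
                                        male_condom = 0.008,
                                        female_sterilization = 0.004,
                                        other_modern = 0.002,
                                        periodic_abstinence = 0.004,
                                        withdrawal = 0.002,
                                        other_traditional = 0.003),
                        use_share = 0.3, rr = 1, lbp = 1) {
  methods <- cp_methods()$label
  using <- methods[-1]
  mix <- matrix(use_share / 10, 35, 10, dimnames = list(15:49, using))
  mix <- cbind(not_using = 1 - use_share, mix)
  sw <- matrix(1 / 9, 10, 10, dimnames = list(using, using))
  diag(sw) <- 0
  cp_parameters(
    method_use_in_2010 = mix,
    pregnancy_not_using_in_2010 = rep(preg_nu, 35),
    pregnancy_not_using_hiv_effect = rep(1, 7),
    age_specific_fertility_rates = rep(0.15, 7),
    scaling_factor_on_monthly_risk_of_pregnancy = rep(1, 7),
    initiation_by_method = init,
    initiation_after_birth = after_birth,
    prob_switch_from = switch_from,
    switch_matrix = sw,
    failure_by_method = fail,
    discontinuation_by_method = disc,
    rr_fail_under25 = rr,
    live_birth_probability = lbp)
}

# every transition, pregnancy and failure probability zero
zero_params <- function(use_share = 0.3) {
  z <- stats::setNames(rep(0, 10), cp_methods()$label[-1])
  flat_params(preg_nu = 0, init = z, fail = z, disc = z, switch_from = z,
              after_birth = z, use_share = use_share)
}

# age structure concentrated on women of one age
single_age_structure <- function(age = 30, sex = "F") {
  data.frame(sex = sex, age = age, prop = 1, stringsAsFactors = FALSE)
}

zero_mortality <- function() {
  m <- default_mortality_schedule()
  m[] <- 0
  m
}
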