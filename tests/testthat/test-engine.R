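test_that("risk formulas combine base, HIV, under-25 and scaling multipliers", {
  p <- flat_params()
  p$pregnancy_not_using_in_2010[] <- 0.10
  p$scaling_factor_on_monthly_risk_of_pregnancy[] <-
    c(1.227, 0.799, 0.829, 0.809, 0.749, 0.645, 0.941)
  p$pregnancy_not_using_hiv_effect[] <- c(1.4, 0.9, 0.8, 0.7, 0.5, 0.4, 0.3)
  p$rr_fail_under25 <- 2.2
  p$failure_by_method["pill"] <- 0.005

  expect_equal(unname(monthly_pregnancy_risk_not_using(17, FALSE, p)), 0.1227)
  expect_equal(unname(monthly_pregnancy_risk_not_using(17, TRUE, p)), 0.17178)
  expect_equal(unname(monthly_failure_risk("pill", 22, p)),
               0.005 * 2.2 * 0.799)
  expect_equal(unname(monthly_failure_risk("pill", 30, p)), 0.005 * 0.809)
  p$failure_by_method["pill"] <- 0
  expect_equal(unname(monthly_failure_risk("pill", 22, p)), 0)
  p$pregnancy_not_using_in_2010[] <- 0
  expect_equal(unname(monthly_pregnancy_risk_not_using(40, TRUE, p)), 0)

  expect_error(monthly_pregnancy_risk_not_using(12, FALSE, p), "15-49")
  expect_error(monthly_failure_risk("not_using", 30, p), "not_using")
})

test_that("initiation probability is multiplicative in age effect and intervention", {
  z <- stats::setNames(rep(0, 10), cp_methods()$label[-1])
  z["injection"] <- 0.02
  p <- flat_params(init = z)
  p$initiation_by_age[] <- 0.5  # +50 percent at every age
  iv <- cp_intervention(pop = c(injection = 2), start_year = 2010)
  I <- initiation_probabilities(p, 30, month = contrasim:::cp_ym(2010, 1),
                                iv = iv)
  expect_equal(unname(I[1, "injection"]), 0.02 * 1.5 * 2)
  # before the intervention start the multiplier is 1
  iv2 <- cp_intervention(pop = c(injection = 2), start_year = 2015)
  I2 <- initiation_probabilities(p, 30, month = contrasim:::cp_ym(2010, 1),
                                 iv = iv2)
  expect_equal(unname(I2[1, "injection"]), 0.02 * 1.5)
  # postpartum contract: 0.2 * 1.5 = 0.3
  p$initiation_after_birth[] <- 0
  p$initiation_after_birth["injection"] <- 0.2
  ivp <- cp_intervention(ppfp = c(injection = 1.5), start_year = 2010)
  expect_equal(unname(postpartum_probabilities(
    p, contrasim:::cp_ym(2010, 1), ivp)["injection"]), 0.3)
})

test_that("zero probabilities mean every woman stays put", {
  p <- zero_params()
  w_nu <- data.frame(age = rep(30, 100), hiv = FALSE)
  out <- step_not_using(w_nu, p)
  expect_true(all(out$kind == "stay"))
  w_us <- data.frame(method = rep("pill", 100), age = 30)
  out <- step_using(w_us, p)
  expect_true(all(out$kind == "stay"))
})

test_that("female sterilization is absorbing even with nonzero table rates", {
  p <- flat_params()
  p$discontinuation_by_method["female_sterilization"] <- 1
  p$prob_switch_from["female_sterilization"] <- 0.9
  p$failure_by_method["female_sterilization"] <- 0
  out <- step_using(data.frame(method = rep("female_sterilization", 500),
                               age = 35), p)
  expect_true(all(out$kind == "stay"))
})

test_that("sequential competing draws reproduce the enumerated distribution", {
  # p_fail 0.01, p_disc 0.1, p_switch 0.2 ->
  # {failure 0.01, discontinue 0.099, switch 0.1782, stay 0.7128}
  fail <- stats::setNames(rep(0, 10), cp_methods()$label[-1])
  fail["pill"] <- 0.01
  disc <- fail; disc["pill"] <- 0.1
  sw <- fail; sw["pill"] <- 0.2
  p <- flat_params(fail = fail, disc = disc, switch_from = sw)
  n <- 200000
  out <- step_using(data.frame(method = rep("pill", n), age = 30), p,
                    u = matrix(contrasim:::cp_runif(99, 0, 1, 1:(4 * n)),
                               n, 4))
  freq <- table(factor(out$kind, c("failure_pregnancy", "discontinue",
                                   "switch", "stay"))) / n
  exp_p <- c(0.01, 0.099, 0.1782, 0.7128)
  se <- sqrt(exp_p * (1 - exp_p) / n)
  expect_true(all(abs(as.numeric(freq) - exp_p) <= 4 * se))
})

test_that("pregnancy resolution schedules, delivers and errors off-schedule", {
  p <- flat_params(lbp = 1)
  women <- data.frame(id = 1:5, preg_start = rep(100L, 5))
  out <- resolve_pregnancy(women, p, month = 109L)
  expect_true(all(out$kind == "birth"))
  expect_true(all(out$newborn_sex %in% c("F", "M")))
  expect_error(resolve_pregnancy(women, p, month = 108L), "off-schedule")
  p$live_birth_probability <- 0
  out <- resolve_pregnancy(women, p, month = 109L)
  expect_true(all(out$kind == "pregnancy_end"))
  expect_true(all(is.na(out$newborn_sex)))
})

test_that("a zero-probability run only delivers the scheduled initial births", {
  p <- zero_params()
  cfg <- cp_config(2000, 2010, 2013, seed = 5)
  r <- run_simulation(cfg, p, zero_mortality())
  s <- r$series
  # births only in the first nine months, from the initial schedule
  expect_true(all(s$births[-(1:9)] == 0))
  expect_equal(sum(s$conceptions), 0)
  expect_equal(sum(s$deaths), 0)
  # no contraception transitions at all: only scheduled births, aging and
  # appointment bookkeeping for prevalent users appear in the log
  kinds <- unique(r$events$kind)
  expect_true(all(kinds %in% c("birth", "age_exit", "initiation_appt",
                               "maintenance_appt")))
  trans <- c("initiate", "discontinue", "switch", "failure_pregnancy",
             "pregnancy", "postpartum_initiate")
  expect_false(any(r$events$kind %in% trans))
})

test_that("identical seeds give identical runs; different seeds differ", {
  p <- generate_default_parameters(1)
  cfg <- cp_config(3000, 2010, 2015, seed = 42)
  r1 <- run_simulation(cfg, p)
  r2 <- run_simulation(cfg, p)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$series, r2$series)
  cfg2 <- cp_config(3000, 2010, 2015, seed = 43)
  r3 <- run_simulation(cfg2, p)
  expect_false(identical(r1$events, r3$events))
})

test_that("event-log replay reconstructs the final population state", {
  p <- generate_default_parameters(2)
  cfg <- cp_config(2500, 2010, 2016, seed = 7)
  r <- run_simulation(cfg, p)
  rep_per <- replay_events(r)
  fin <- r$population$persons
  rep_per <- rep_per[order(rep_per$id), ]
  cols <- c("id", "alive", "method", "pregnant", "preg_start", "last_appt")
  expect_equal(rep_per[, cols], fin[, cols], ignore_attr = TRUE)
})

test_that("no contraception transitions for men, children or the dead", {
  p <- generate_default_parameters(2)
  cfg <- cp_config(2500, 2010, 2016, seed = 7)
  r <- run_simulation(cfg, p)
  trans <- c("initiate", "discontinue", "switch", "failure_pregnancy",
             "pregnancy", "postpartum_initiate")
  ev <- r$events[r$events$kind %in% trans, ]
  per <- r$population$persons
  i <- match(ev$person_id, per$id)
  expect_true(all(per$sex[i] == "F"))
  # nobody transitions after their death month
  deaths <- r$events[r$events$kind == "death", ]
  dm <- stats::setNames(deaths$month, deaths$person_id)
  after <- ev$month > dm[as.character(ev$person_id)]
  expect_true(all(!after, na.rm = TRUE))
  # conservation: state counts plus pregnancy orthogonality
  s <- r$series
  methods <- cp_methods()$label
  expect_equal(rowSums(s[, methods]), s$women_1549)
})

test_that("stronger initiation multipliers weakly reduce pregnancies under CRN", {
  p <- generate_default_parameters(1)
  iv <- cp_intervention(pop = 3, ppfp = 2, start_year = 2013)
  cfg0 <- cp_config(4000, 2010, 2017, seed = 3)
  cfg1 <- cp_config(4000, 2010, 2017, seed = 3, intervention = iv)
  r0 <- run_simulation(cfg0, p)
  r1 <- run_simulation(cfg1, p)
  s0 <- r0$series; s1 <- r1$series
  post <- s0$ym >= contrasim:::cp_ym(2013, 1)
  using0 <- s0$women_1549 - s0$not_using
  using1 <- s1$women_1549 - s1$not_using
  expect_true(all(using1[post] >= using0[post]))
  expect_lte(sum(s1$conceptions), sum(s0$conceptions))
})
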