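test_that("initialization handles empty and degenerate cases", {
  p <- generate_default_parameters(1)
  pop <- initialize_population(0, p = p)
  expect_s3_class(pop, "cp_population")
  expect_equal(nrow(pop$persons), 0)
  expect_error(initialize_population(-5, p = p), "nonnegative")

  # a baseline mix of pure non-use puts every woman on not_using
  pz <- zero_params(use_share = 0)
  pop <- initialize_population(500, single_age_structure(25), pz, seed = 3)
  expect_true(all(pop$persons$method == 1L))
  expect_false(any(pop$persons$pregnant))
})

test_that("assigned method shares match the baseline row within 3 binomial SE", {
  p <- generate_default_parameters(1)
  n <- 50000
  pop <- initialize_population(n, single_age_structure(30), p, seed = 11)
  counts <- tabulate(pop$persons$method, 11)
  target <- p$method_use_in_2010["30", ]
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(counts / n - target) <= 3 * se + 1e-12))
})

test_that("initial birth scheduling matches the fertility-rate expectation", {
  p <- generate_default_parameters(1)
  # zero fertility: no events
  p0 <- p
  p0$age_specific_fertility_rates[] <- 0
  pop <- initialize_population(1000, single_age_structure(22), p0, seed = 2)
  sb <- schedule_initial_births(pop, p0, seed = 2)
  expect_equal(nrow(sb$events), 0)

  # 1,000 women aged 20-24 at the printed rate 0.239:
  # expected scheduled births 1000 * 0.239 * 9/12 = 179.25
  pop <- initialize_population(1000, single_age_structure(22), p, seed = 2)
  sb <- schedule_initial_births(pop, p, seed = 2)
  pr <- 0.239 * 9 / 12
  se <- sqrt(1000 * pr * (1 - pr))
  expect_lt(abs(nrow(sb$events) - 179.25), 3 * se)
  # scheduled women are pregnant with a consistent backdated conception
  per <- sb$population$persons
  i <- match(sb$events$person_id, per$id)
  expect_true(all(per$pregnant[i]))
  expect_equal(per$preg_start[i] + 9L, sb$events$birth_ym)
  expect_true(all(sb$events$birth_ym >= pop$date &
                    sb$events$birth_ym <= pop$date + 8L))
  # determinism
  sb2 <- schedule_initial_births(pop, p, seed = 2)
  expect_identical(sb$events, sb2$events)
})

test_that("monthly mortality composes to the annual probability", {
  p <- generate_default_parameters(1)
  pop <- initialize_population(10000, single_age_structure(40, "M"), p,
                               seed = 4)
  # all-zero schedule: nobody dies
  r <- apply_mortality(pop, zero_mortality(), seed = 1)
  expect_equal(r$deaths, 0)
  # annual q = 1: everyone dies in the first month
  m1 <- zero_mortality(); m1[] <- 1
  r <- apply_mortality(pop, m1, seed = 1)
  expect_equal(r$deaths, 10000)
  # annual q = 0.012 over 12 months kills ~120 of 10,000
  mq <- zero_mortality(); mq[] <- 0.012
  for (k in 1:12) pop <- apply_mortality(pop, mq, seed = k)$population
  dead <- sum(!pop$persons$alive)
  se <- sqrt(10000 * 0.012 * 0.988)
  expect_lt(abs(dead - 120), 3 * se)
})

test_that("aging is monotone and evicts women crossing 50", {
  p <- generate_default_parameters(1)
  # a woman aged 49 years 11 months on a method
  per <- contrasim:::cp_new_persons(1L, "F", contrasim:::cp_ym(2010, 1) -
                                      (49L * 12L + 11L), method = 4L)
  pop <- contrasim:::cp_population(per, contrasim:::cp_ym(2010, 1))
  expect_equal(contrasim:::cp_age_years(pop), 49L)
  pop2 <- advance_age(pop)
  expect_equal(contrasim:::cp_age_years(pop2), 50L)
  expect_equal(pop2$persons$method, 1L)  # no longer in the risk set

  pop3 <- initialize_population(200, p = p, seed = 9)
  a0 <- contrasim:::cp_age_years(pop3)
  a1 <- contrasim:::cp_age_years(advance_age(pop3))
  expect_true(all(a1 >= a0))
  # mean age advances by exactly one month absent births and deaths
  mean_months0 <- mean(pop3$date - pop3$persons$dob)
  pop4 <- advance_age(pop3)
  expect_equal(mean(pop4$date - pop4$persons$dob), mean_months0 + 1)
})

test_that("missing mortality stratum is reported", {
  p <- generate_default_parameters(1)
  pop <- initialize_population(10, single_age_structure(30), p, seed = 1)
  sched <- zero_mortality()[, "F", drop = FALSE]  # drop the male column
  popm <- initialize_population(10, single_age_structure(30, "M"), p, seed = 1)
  expect_error(apply_mortality(popm, sched), "stratum")
})
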