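test_that("synthetic default embeds the published scalar values and validates", {
  p <- generate_default_parameters(seed = 1)
  expect_equal(unname(p$pregnancy_not_using_hiv_effect),
               c(1.4, 0.9, 0.8, 0.7, 0.5, 0.4, 0.3))
  expect_equal(p$pregnancy_not_using_hiv_effect[["15-19"]], 1.4)
  expect_equal(unname(p$age_specific_fertility_rates),
               c(0.144, 0.239, 0.213, 0.174, 0.123, 0.061, 0.022))
  expect_equal(p$age_specific_fertility_rates[["20-24"]], 0.239)
  expect_equal(unname(p$scaling_factor_on_monthly_risk_of_pregnancy),
               c(1.227, 0.799, 0.829, 0.809, 0.749, 0.645, 0.941))
  expect_equal(p$rr_fail_under25, 2.2)
  expect_equal(p$days_between_appts_for_maintenance[["IUD"]], 4383)
  expect_equal(p$days_between_appts_for_maintenance[["implant"]], 1461)
  expect_equal(unname(p$days_between_appts_for_maintenance[
    c("injection", "male_condom", "other_modern", "pill")]), rep(91, 4))
  expect_true(validate_parameters(p)$ok)
  # injection is the highest-initiation modern method at every age
  im <- p$initiation_by_method
  expect_true(all(im[, "injection"] == apply(im, 1, max)))
})

test_that("default generation is deterministic per seed", {
  expect_identical(generate_default_parameters(7),
                   generate_default_parameters(7))
  p1 <- generate_default_parameters(1)
  p2 <- generate_default_parameters(2)
  expect_false(identical(p1$method_use_in_2010, p2$method_use_in_2010))
  # printed scalars do not depend on the seed
  expect_identical(p1$age_specific_fertility_rates,
                   p2$age_specific_fertility_rates)
})

test_that("validation collects every violation, not just the first", {
  p <- generate_default_parameters(1)
  p$switch_matrix[2, ] <- p$switch_matrix[2, ] * 0.9
  p$failure_by_method["pill"] <- 1.5
  v <- validate_parameters(p)
  expect_false(v$ok)
  expect_true("switch_rows_sum_1" %in% v$violations$rule)
  expect_true(any(v$violations$rule == "probability_range" &
                    grepl("failure_by_method", v$violations$location)))
  expect_gte(nrow(v$violations), 2)
})

test_that("probabilities of a valid set are in range and rows normalized", {
  for (s in 1:3) {
    p <- generate_default_parameters(s)
    expect_true(all(p$method_use_in_2010 >= 0 & p$method_use_in_2010 <= 1))
    expect_equal(unname(rowSums(p$method_use_in_2010)), rep(1, 35))
    expect_equal(unname(rowSums(p$switch_matrix)), rep(1, 10),
                 tolerance = 1e-12)
    expect_true(all(diag(p$switch_matrix) == 0))
  }
})

test_that("sterilization age restriction matches the two-age hand example", {
  p <- flat_params(init = c(pill = 0.09, IUD = 0, injection = 0,
                            implant = 0, male_condom = 0,
                            female_sterilization = 0.01, other_modern = 0,
                            periodic_abstinence = 0, withdrawal = 0,
                            other_traditional = 0))
  w <- rep(0, 35)
  w[c(25, 35) - 14] <- 1  # equal weight at ages 25 and 35
  out <- apply_sterilization_age_restriction(p, eligible_age = 30,
                                             age_weights = w)
  im <- out$initiation_by_method
  expect_equal(im["25", "female_sterilization"], 0)
  expect_equal(im["25", "pill"], 0.10)
  expect_equal(im["35", "female_sterilization"], 0.02)
  expect_equal(im["35", "pill"], 0.08)
  # expected sterilizations per woman preserved at 0.01
  expect_equal(sum(w * im[, "female_sterilization"]) / sum(w), 0.01)
})

test_that("sterilization restriction boundary and degenerate cases", {
  z <- stats::setNames(rep(0, 10), cp_methods()$label[-1])
  z["pill"] <- 0.05
  p0 <- flat_params(init = z)  # sterilization probability zero everywhere
  expect_identical(apply_sterilization_age_restriction(p0)$initiation_by_method,
                   p0$initiation_by_method)
  # all weight at eligible ages: no scaling, only the under-30 zeroing
  p <- flat_params()
  w <- c(rep(0, 15), rep(1, 20))  # ages 30-49
  out <- apply_sterilization_age_restriction(p, 30, w)
  expect_equal(out$initiation_by_method["35", "female_sterilization"],
               p$initiation_by_method["35", "female_sterilization"])
  expect_equal(out$initiation_by_method["20", "female_sterilization"], 0)
  # impossible redistribution errors
  z2 <- z; z2["female_sterilization"] <- 0.9
  expect_error(apply_sterilization_age_restriction(
    flat_params(init = z2), 30, c(rep(1, 34), 1)), "exceeds")
})

test_that("sterilization restriction preserves population expectations", {
  p <- generate_default_parameters(3)
  set.seed(42)
  for (rep_i in 1:10) {
    w <- stats::runif(35)
    im0 <- p$initiation_by_method
    im1 <- apply_sterilization_age_restriction(p, 30, w)$initiation_by_method
    expect_equal(sum(w * rowSums(im1)), sum(w * rowSums(im0)),
                 tolerance = 1e-12)
    expect_equal(sum(w * im1[, "female_sterilization"]),
                 sum(w * im0[, "female_sterilization"]), tolerance = 1e-12)
    expect_true(all(im1[1:15, "female_sterilization"] == 0))
  }
})

test_that("save/load round trip is lossless and errors are named", {
  p <- generate_default_parameters(5)
  dir <- withr::local_tempdir()
  save_parameters(p, dir)
  q <- load_parameters(dir)
  expect_equal(q, p, tolerance = 1e-15)

  file.remove(file.path(dir, "switch_matrix.csv"))
  expect_error(load_parameters(dir), "switch_matrix")

  save_parameters(p, dir)
  writeLines("from,pill", file.path(dir, "switch_matrix.csv"))
  expect_error(load_parameters(dir), "switch_matrix")

  # out-of-range probability is rejected at load time
  save_parameters(p, dir)
  fb <- utils::read.csv(file.path(dir, "failure_by_method.csv"))
  fb$value[1] <- 1.5
  utils::write.csv(fb, file.path(dir, "failure_by_method.csv"),
                   row.names = FALSE)
  expect_error(load_parameters(dir), "validation")
})
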