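test_that("weighted unit costs reproduce the printed pill and implant values", {
  pill <- weighted_unit_cost(data.frame(unit_cost = c(531.1, 340.4),
                                        share = c(0.8, 0.2), units = 1))
  expect_equal(pill, 492.96)
  expect_equal(round(pill), 493)
  implant <- weighted_unit_cost(data.frame(unit_cost = c(449.05, 622.12),
                                           share = c(0.5, 0.5),
                                           units = c(2, 1)))
  expect_equal(implant, 760.11)
  expect_equal(round(implant), 760)
  # a single alternative with share 1 is its own cost
  expect_equal(weighted_unit_cost(data.frame(unit_cost = 100, share = 1,
                                             units = 2)), 200)
  expect_error(weighted_unit_cost(data.frame(unit_cost = 1, share = 0.5,
                                             units = 1)), "sum to 1")
})

test_that("package costs are the sums of their printed item rows", {
  expect_equal(package_cost("injection"), 481 + 37 + 32 + 85 + 16)  # 651
  expect_equal(package_cost("male_condom"), 30 * 21)                # 630
  expect_equal(package_cost("IUD"), 2 * 37 + 26)
  expect_equal(package_cost("pill"), 3.75 * 493)
  expect_equal(package_cost("other_modern"), 30 * 22)
  expect_equal(package_cost("initiation"), 32)
  expect_error(package_cost("withdrawal"), "no consumable package")
  # empty package costs nothing
  empty <- cp_consumables()[0, ]
  expect_equal(sum(empty$units * empty$unit_cost_mwk), 0)
})

test_that("currency conversion reproduces printed USD unit costs", {
  expect_equal(round(convert_currency(1558), 2), 1.97)
  expect_equal(round(convert_currency(493), 2), 0.62)
  expect_equal(convert_currency(0), 0)
  # round trip before display rounding
  x <- 1234.56
  expect_equal(convert_currency(x) * 790, x, tolerance = 1e-12)
})

test_that("maintenance appointments trigger strictly beyond the interval", {
  p <- generate_default_parameters(1)
  expect_false(maintenance_due(91, "injection", p))
  expect_true(maintenance_due(92, "injection", p))
  expect_true(maintenance_due(NA, "injection", p))  # never attended: due
  expect_false(maintenance_due(1461, "implant", p))
  expect_true(maintenance_due(1462, "implant", p))
  expect_error(maintenance_due(10, "withdrawal", p), "maintainable")
  # an implant user needs about one maintenance visit per four years
  expect_equal(p$days_between_appts_for_maintenance[["implant"]] / 365.25, 4)
})

test_that("implementation costs scale proportionally with the 15-49 population", {
  cc <- cp_cost_config(base_population_15_49 = 8e6)
  expect_equal(implementation_cost(2023, 8e6, cc, "Pop"), 2400e6)
  expect_equal(implementation_cost(2023, 12e6, cc, "Pop"), 3600e6)
  expect_equal(implementation_cost(2023, 8e6, cc, "PPFP"), 264e6)
  expect_error(implementation_cost(2023, 0, cc, "Pop"))
})

test_that("per-capita summary reproduces the published arithmetic", {
  pc <- per_capita_summary(231.2e6, 26948785, 28)
  expect_equal(round(pc[["usd_per_capita_per_year"]], 2), 0.31)
  expect_equal(round(pc[["pct_of_total_health_expenditure"]], 1), 0.9)
  pc0 <- per_capita_summary(0, 1e6, 10)
  expect_equal(unname(pc0), c(0, 0))
})

test_that("cost ledger is additive and zero usage costs nothing", {
  p <- generate_default_parameters(1)
  iv <- cp_intervention(pop = 2, ppfp = 2, start_year = 2013)
  cfg <- cp_config(3000, 2010, 2016, seed = 2, intervention = iv,
                   scale_target_population = 3e6)
  r <- run_simulation(cfg, p)
  cs <- summarize_costs(r, list("2013-2016"), cp_cost_config())
  led <- cs$ledger
  modern <- led$mwk[led$category == "modern_total"]
  per_method <- sum(led$mwk[led$category %in% cp_methods()$label])
  expect_equal(modern, per_method)
  grand <- led$mwk[led$category == "grand_total"]
  imp <- led$mwk[led$category == "implementation_total"]
  expect_equal(grand, modern + imp)
  expect_equal(imp, led$mwk[led$category == "Pop_implementation"] +
                 led$mwk[led$category == "PPFP_implementation"])
  expect_equal(led$usd, led$mwk / 790)
  expect_error(summarize_costs(r, list("2030-2040")), "outside")

  # no users, no interventions: zero consumable and implementation costs
  pz <- zero_params(use_share = 0)
  rz <- run_simulation(cp_config(500, 2010, 2012, seed = 1), pz,
                       zero_mortality())
  csz <- summarize_costs(rz, list("2011-2012"))
  expect_true(all(csz$ledger$mwk == 0))
})
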