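test_that("the base-case scenario equals the default pipeline", {
  sc <- run_scenario("base_case")
  m <- base_model()
  expect_equal(sc$incremental_costs$total, m$incremental_costs$total)
  expect_equal(unclass(sc$events)[1:12], unclass(m$events)[1:12])
  expect_error(run_scenario("nonexistent"), "nonexistent")
})

test_that("the mortality scenario combines cohort baseline with trial effect", {
  sc <- run_scenario("mortality_rct")
  expect_equal(sc$model$clinical$p_death_usual, 0.172)
  expect_equal(sc$model$clinical$rr_death, 0.24)
  expect_equal(-sc$events$deaths, 172 * (1 - 0.24))
  expect_equal(round(-sc$events$deaths), 131)
  # more survivors than in the base case, so smaller cost savings
  expect_gt(sc$incremental_costs$total, base_model()$incremental_costs$total)
  expect_lt(sc$incremental_costs$total, 0)
})

test_that("lower- and higher-cost scenarios bracket the base case", {
  base <- base_model()$incremental_costs$total
  lo <- run_scenario("lower_cost")$incremental_costs$total
  hi <- run_scenario("higher_cost")$incremental_costs$total
  expect_lt(lo, base)   # greater savings
  expect_gt(hi, base)   # smaller savings
  expect_lt(hi, 0)      # still cost-saving
})

test_that("scenario presets reproduce base case when overrides are removed", {
  presets <- scenario_presets()
  for (nm in names(presets)) {
    cl <- unclass(run_scenario(nm)$model$clinical)
    cl[names(presets[[nm]])] <-
      unclass(clinical_params())[names(presets[[nm]])]
    m <- ehmd_model(clinical = do.call(clinical_params, cl))
    expect_equal(m$incremental_costs$total,
                 base_model()$incremental_costs$total)
  }
})

test_that("sweeps hold everything but the swept parameter fixed", {
  m <- base_model()
  sw <- sweep_param(m, "p_nec_usual", c(0.02, 0.05, 0.167))
  expect_s3_class(sw, "ehmd_sweep")
  expect_equal(nrow(sw), 3)
  # at the base-case value the sweep matches the base-case run
  expect_equal(sw$incremental_cost_total[sw$p_nec_usual == 0.167],
               m$incremental_costs$total)
  # death and sepsis columns are untouched by the NEC sweep
  expect_equal(unique(sw$inc_deaths), m$events$deaths)
  expect_equal(unique(sw$inc_sepsis), m$events$sepsis)
  # NEC cases avoided at 5% and 2% baseline incidence
  expect_equal(-sw$inc_nec[sw$p_nec_usual == 0.05], 34.5)
  expect_equal(round(-sw$inc_nec[sw$p_nec_usual == 0.05]), 34)
  expect_equal(round(-sw$inc_nec[sw$p_nec_usual == 0.02]), 14)

  expect_error(sweep_param(m, "p_nec_usual", c(0.05, 0.02)),
               "strictly increasing")
  expect_error(sweep_param(m, "p_nec_usual", c(0.05, 1.5)), "1.5")
})

test_that("incremental total cost is affine in the baseline NEC incidence", {
  m <- base_model()
  grid <- seq(0.01, 0.25, by = 0.04)
  sw <- sweep_param(m, "p_nec_usual", grid)
  y <- sw$incremental_cost_total
  slopes <- diff(y) / diff(grid)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-9)
})

test_that("threshold analysis agrees with the closed form and flags bounds", {
  m <- base_model()
  th <- threshold_incidence(m, "p_nec_usual")
  expect_identical(th$status, "interior")
  expect_equal(th$value, th$closed_form, tolerance = 1e-6)
  # independent cross-check with a generic root finder
  f <- function(v) predict(m, data.frame(p_nec_usual = v))$incremental_cost_total
  ur <- stats::uniroot(f, c(1e-6, 0.9), tol = 1e-10)$root
  expect_equal(th$value, ur, tolerance = 1e-6)
  # the model is cost-saving even with zero late-onset sepsis incidence
  ths <- threshold_incidence(m, "p_sepsis_usual")
  expect_identical(ths$status, "always-saving")
  expect_lt(ths$f_lower, 0)
  # with no incremental diet cost the break-even incidence is essentially 0
  m0 <- ehmd_model(costs = cost_params(cost_diet_usual =
                                         diet_cost_ehmd(cost_params())))
  th0 <- threshold_incidence(m0, "p_nec_usual")
  expect_lt(th0$value, 0.005)
  expect_equal(th0$percent, 0)
})

test_that("sweep plots render without error", {
  sw <- sweep_param(base_model(), "p_nec_usual", c(0.02, 0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(sw))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
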