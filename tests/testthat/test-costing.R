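test_that("EHMD diet cost follows the fortifier mixing arithmetic", {
  co <- cost_params()
  expect_equal(diet_cost_ehmd(co),
               oracle_diet_cost(1943, 883, 187.50, 70, 183))
  expect_equal(round(diet_cost_ehmd(co)), 7731)
  expect_equal(incremental_diet_cost(co), diet_cost_ehmd(co) - 226)
  expect_equal(round(incremental_diet_cost(co)), 7505)

  # 700 mL of mother's milk only: 10 fractional vials, no donor-milk cost
  co2 <- cost_params(vol_mother_ehmd_ml = 700, vol_donor_ehmd_ml = 0)
  expect_equal(diet_cost_ehmd(co2), 10 * 187.50)
  expect_equal(diet_cost_ehmd(cost_params(vol_mother_ehmd_ml = 0,
                                          vol_donor_ehmd_ml = 0)), 0)
  expect_equal(incremental_diet_cost(cost_params(cost_diet_usual = 0)),
               diet_cost_ehmd(co))
})

test_that("diet cost is linear in each volume and unit price", {
  co <- unclass(cost_params())
  for (f in c("vol_mother_ehmd_ml", "vol_donor_ehmd_ml",
              "price_fortifier_vial", "price_donor_milk_per_l")) {
    h <- 10
    up <- co; up[[f]] <- up[[f]] + h
    up2 <- co; up2[[f]] <- up2[[f]] + 2 * h
    d1 <- diet_cost_ehmd(do.call(cost_params, up)) -
      diet_cost_ehmd(do.call(cost_params, co))
    d2 <- diet_cost_ehmd(do.call(cost_params, up2)) -
      diet_cost_ehmd(do.call(cost_params, up))
    expect_equal(d1, d2, tolerance = 1e-10)
  }
})

test_that("arm cost breakdowns attach the per-event costs additively", {
  cl <- clinical_params()
  co <- cost_params()
  u <- run_arm(cl, econ_settings(), "usual")
  cb <- arm_costs(u, co)
  expect_equal(cb$diet, 226)
  expect_equal(cb$baseline_stay, 49660)
  # independent arithmetic oracle for the usual-care NEC+sepsis cost
  expect_equal(cb$nec_and_sepsis,
               (167 * 0.635 * 229431 + 167 * 0.365 * 85734 +
                  303 * 12413) / 1000)
  expect_equal(cb$total,
               cb$diet + cb$baseline_stay + cb$nec_and_sepsis + cb$sequelae)

  # no events at all: only diet and the baseline stay remain
  cl0 <- clinical_params(p_nec_usual = 0, p_sepsis_usual = 0,
                         p_death_usual = 0, p_bpd_usual = 0,
                         p_rop_usual = 0, p_cp_base = 0)
  cb0 <- arm_costs(run_arm(cl0, econ_settings(), "usual"), co)
  expect_equal(cb0$total, 226 + 49660)
})

test_that("incremental cost components difference exactly and stay additive", {
  m <- base_model()
  inc <- m$incremental_costs
  expect_equal(inc$baseline_stay, 0)
  expect_equal(inc$total,
               inc$diet + inc$baseline_stay + inc$nec_and_sepsis +
                 inc$sequelae)
  same <- incremental_costs(m$costs_by_arm$usual, m$costs_by_arm$usual)
  expect_true(all(unlist(same[c("diet", "baseline_stay", "nec_and_sepsis",
                                "sequelae", "total")]) == 0))
  # additivity holds for random parameter sets too
  draws <- draw_params(param_distributions(seed = 3), 20)
  for (d in draws) {
    mm <- ehmd_model(d$clinical, d$costs)
    ic <- mm$incremental_costs
    expect_equal(ic$total, ic$diet + ic$nec_and_sepsis + ic$sequelae)
  }
})

test_that("with all event costs zero the incremental total is the diet cost", {
  co <- cost_params(cost_nec_surgical = 0, cost_nec_medical = 0,
                    cost_sepsis = 0, cost_bpd = 0, cost_rop = 0,
                    cost_cp_lifetime_payer = 0)
  m <- ehmd_model(costs = co)
  expect_equal(m$incremental_costs$total, incremental_diet_cost(co))
})

test_that("the societal view extends the payer view additively", {
  co <- cost_params(societal = synthetic_societal())
  m_pay <- ehmd_model(costs = co, societal = FALSE)
  m_soc <- ehmd_model(costs = co, societal = TRUE)
  for (arm in c("usual", "ehmd")) {
    pb <- m_pay$costs_by_arm[[arm]]
    sb <- m_soc$costs_by_arm[[arm]]
    expect_gte(sb$societal, 0)
    expect_equal(sb$total, pb$total + sb$societal)
    # hand-built societal component for this arm
    a <- m_soc$arms[[arm]]
    soc <- synthetic_societal()
    expect_equal(sb$societal,
                 (a$cp * (soc$cost_cp_lifetime_societal - 147268) +
                    a$iq_points_lost_total * soc$earnings_loss_per_iq_point +
                    a$rop * soc$rop_productivity_loss) / 1000)
  }
  # incremental view mismatch and missing block are errors
  expect_error(incremental_costs(m_soc$costs_by_arm$ehmd,
                                 m_pay$costs_by_arm$usual), "breakdown")
  expect_error(ehmd_model(societal = TRUE), "societal")
})
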