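test_that("relative risks scale baselines and clamp with a warning", {
  expect_equal(apply_relative_risk(0.167, 0.31), 0.05177)
  expect_equal(apply_relative_risk(0.42, 1), 0.42)
  expect_warning(out <- apply_relative_risk(0.9, 2), "clamp")
  expect_equal(out, 1)
})

test_that("CP probability follows the NEC/sepsis history with the max rule", {
  expect_equal(cp_probability(0.148, 1.55, FALSE, FALSE), 0.148)
  expect_equal(cp_probability(0.148, 1.55, FALSE, TRUE), 0.148)
  expect_equal(cp_probability(0.148, 1.55, TRUE, FALSE), 0.148 * 1.55)
  # both events: the NEC value is the larger and applies
  expect_equal(cp_probability(0.148, 1.55, TRUE, TRUE), 0.148 * 1.55)
  # strict odds-scale conversion is available as a switch
  odds <- 0.148 / (1 - 0.148) * 1.55
  expect_equal(cp_probability(0.148, 1.55, TRUE, FALSE, or_method = "odds"),
               odds / (1 + odds))
  expect_equal(round(cp_probability(0.148, 1.55, TRUE, FALSE,
                                    or_method = "odds"), 4), 0.2121)
})

test_that("IQ loss takes the NEC value, never additive", {
  expect_equal(iq_loss(TRUE, TRUE, 11, 9), 11)
  expect_equal(iq_loss(TRUE, FALSE, 11, 9), 11)
  expect_equal(iq_loss(FALSE, TRUE, 11, 9), 9)
  expect_equal(iq_loss(FALSE, FALSE, 11, 9), 0)
})

test_that("arm evaluation reproduces the expected counts", {
  cl <- clinical_params()
  usual <- run_arm(cl, econ_settings(), "usual")
  expect_equal(usual$deaths, 172)
  expect_equal(usual$nec_total, 167)
  expect_equal(usual$nec_surgical, 167 * 0.635)
  expect_equal(usual$sepsis, 303)
  expect_equal(usual$bpd, 828 * 0.563)
  expect_equal(usual$sbs, 167 * 0.635 * 0.157)

  ehmd <- run_arm(cl, econ_settings(), "ehmd")
  expect_equal(ehmd$deaths, 172 * 0.79)
  expect_equal(ehmd$nec_total, 167 * 0.31)
  expect_equal(ehmd$nec_surgical, 167 * 0.635 * 0.1132)
  # joint NEC-and-sepsis occurrence is the product of the marginals
  expect_equal(ehmd$nec_and_sepsis, 1000 * 0.05177 * (0.303 * 0.87))
})

test_that("zero baselines give an event-free surviving cohort", {
  cl <- clinical_params(p_nec_usual = 0, p_sepsis_usual = 0,
                        p_death_usual = 0, p_bpd_usual = 0, p_rop_usual = 0,
                        p_cp_base = 0)
  for (arm in c("usual", "ehmd")) {
    a <- run_arm(cl, econ_settings(), arm)
    expect_equal(a$survivors, 1000)
    for (f in c("deaths", "nec_total", "sepsis", "bpd", "rop", "cp", "sbs"))
      expect_equal(a[[f]], 0)
  }
})

test_that("with certain death, sequelae vanish but NEC/sepsis are unchanged", {
  cl <- clinical_params(p_death_usual = 1, rr_death = 1)
  for (arm in c("usual", "ehmd")) {
    a <- run_arm(cl, econ_settings(), arm)
    expect_equal(a$survivors, 0)
    expect_equal(a$bpd, 0)
    expect_equal(a$rop, 0)
    expect_equal(a$cp, 0)
  }
  expect_equal(run_arm(cl, econ_settings(), "usual")$nec_total, 167)
  expect_equal(run_arm(cl, econ_settings(), "ehmd")$sepsis, 303 * 0.87)
})

test_that("arm results satisfy the structural invariants for random inputs", {
  draws <- draw_params(param_distributions(concentration = 5,
                                           rr_sdlog = 0.4, seed = 11), 60)
  for (d in draws) {
    for (arm in c("usual", "ehmd")) {
      a <- run_arm(d$clinical, econ_settings(), arm)
      expect_equal(a$deaths + a$survivors, a$cohort_size)
      expect_equal(a$nec_medical + a$nec_surgical, a$nec_total)
      expect_lte(a$nec_and_sepsis, min(a$nec_total, a$sepsis) + 1e-9)
      expect_lte(a$sbs, a$nec_surgical + 1e-9)
      for (f in c("bpd", "rop", "cp"))
        expect_lte(a[[f]], a$survivors + 1e-9)
      counts <- unlist(a[c("deaths", "survivors", "nec_total", "nec_medical",
                           "nec_surgical", "sepsis", "nec_and_sepsis",
                           "bpd", "rop", "cp", "sbs")])
      expect_true(all(counts >= -1e-9 & counts <= a$cohort_size + 1e-9))
    }
  }
})

test_that("null treatment effect gives exactly zero incremental events", {
  cl <- clinical_params(rr_nec = 1, rr_sepsis = 1, rr_death = 1, rr_bpd = 1,
                        rr_rop = 1, rr_nec_surgical = 1)
  m <- ehmd_model(clinical = cl)
  for (f in c("deaths", "survivors", "nec_total", "nec_medical",
              "nec_surgical", "sepsis", "nec_and_sepsis", "bpd", "rop",
              "cp", "sbs", "iq_points_lost_total"))
    expect_identical(m$events[[f]], 0)
})

test_that("incremental NEC count is linear in the baseline with negative slope", {
  m <- base_model()
  grid <- c(0.02, 0.08, 0.14, 0.20)
  inc <- predict(m, data.frame(p_nec_usual = grid))$inc_nec
  slopes <- diff(inc) / diff(grid)
  expect_lt(max(slopes), 0)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-10)
  expect_equal(slopes[1], -(1 - 0.31) * 1000)
})

test_that("incremental results difference the arms exactly and check sizes", {
  cl <- clinical_params()
  e <- run_arm(cl, econ_settings(), "ehmd")
  u <- run_arm(cl, econ_settings(), "usual")
  inc <- incremental_events(e, u)
  expect_equal(inc$deaths, e$deaths - u$deaths)
  expect_equal(inc$rop, e$rop - u$rop)
  same <- incremental_events(u, u)
  expect_true(all(unlist(same[c("deaths", "nec_total", "sepsis", "bpd",
                                "rop", "cp", "sbs")]) == 0))
  u2 <- run_arm(cl, econ_settings(cohort_size = 500), "usual")
  expect_error(incremental_events(e, u2), "cohort sizes")
})
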