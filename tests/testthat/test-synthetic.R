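test_that("parameter draws are reproducible and validated", {
  d <- param_distributions(seed = 99)
  a <- draw_params(d, 5)
  b <- draw_params(d, 5)
  expect_equal(a, b)
  for (x in a) {
    expect_s3_class(x$clinical, "ehmd_clinical")
    expect_s3_class(x$costs, "ehmd_costs")
  }
  expect_true(attr(a, "clamp_count") >= 0)
})

test_that("degenerate distributions return the base values exactly", {
  d <- param_distributions(concentration = Inf, rr_sdlog = 0, cost_cv = 0,
                           seed = 1)
  x <- draw_params(d, 2)[[1]]
  expect_equal(unclass(x$clinical), unclass(clinical_params()))
  expect_equal(unclass(x$costs), unclass(cost_params()))
  expect_error(param_distributions(concentration = 0), "concentration")
  expect_error(param_distributions(cost_cv = -1), "cost_cv")
})

test_that("Beta draws match their specified mean", {
  d <- param_distributions(concentration = 100, seed = 7)
  draws <- draw_params(d, 1000)
  p <- vapply(draws, function(x) x$clinical$p_nec_usual, numeric(1))
  se <- sqrt(0.167 * (1 - 0.167) / (100 + 1)) / sqrt(1000)
  expect_lt(abs(mean(p) - 0.167), 3 * se)
})

test_that("a misspecified spread surfaces through the clamp count", {
  # huge relative-risk spread must trigger validity clamping, not rejection
  d <- param_distributions(rr_sdlog = 2, seed = 5)
  draws <- draw_params(d, 200)
  expect_length(draws, 200)
  expect_gt(attr(draws, "clamp_count"), 0)
})

test_that("microsimulation converges to the deterministic expectations", {
  cl <- clinical_params()
  co <- cost_params()
  ms <- microsimulate(cl, co, n = 50000, seed = 21)
  for (arm in c("usual", "ehmd")) {
    det <- run_arm(cl, econ_settings(), arm)
    sim <- ms[[arm]]$arm
    for (f in c("deaths", "nec_total", "nec_surgical", "sepsis", "bpd",
                "rop", "cp", "sbs")) {
      p <- det[[f]] / 1000
      se <- sqrt(p * (1 - p) / ms[[arm]]$n) * 1000
      expect_lt(abs(sim[[f]] - det[[f]]), 3 * se + 1e-9)
    }
    # simulated mean cost close to the deterministic per-infant cost
    detc <- arm_costs(det, co)
    expect_equal(ms[[arm]]$costs$total, detc$total,
                 tolerance = 0.02)
  }
})

test_that("microsimulated arms are exchangeable under a null effect", {
  cl <- clinical_params(rr_nec = 1, rr_sepsis = 1, rr_death = 1, rr_bpd = 1,
                        rr_rop = 1, rr_nec_surgical = 1)
  ms <- microsimulate(cl, cost_params(), n = 40000, seed = 13)
  for (f in c("deaths", "nec_total", "sepsis", "bpd", "rop")) {
    p <- run_arm(cl, econ_settings(), "usual")[[f]] / 1000
    se <- sqrt(2 * p * (1 - p) / 40000) * 1000
    expect_lt(abs(ms$ehmd$arm[[f]] - ms$usual$arm[[f]]), 3 * se)
  }
})

test_that("microsimulation error shrinks at the Monte-Carlo rate", {
  cl <- clinical_params()
  det <- run_arm(cl, econ_settings(), "usual")$nec_total
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    ms <- microsimulate(cl, cost_params(), n = n, seed = 17)
    abs(ms$usual$arm$nec_total - det)
  }, numeric(1))
  # |error| * sqrt(n) stays bounded by a few binomial SDs (per 1000 units)
  sd1 <- sqrt(0.167 * (1 - 0.167)) * 1000
  expect_true(all(err * sqrt(c(1e3, 1e4, 1e5)) < 4 * sd1))
})

test_that("PSA output brackets the deterministic base case", {
  d <- param_distributions(seed = 31)
  psa <- run_psa(d, 120)
  expect_equal(nrow(psa), 120)
  base <- base_model()$incremental_costs$total
  expect_lt(min(psa$incremental_cost_total), base)
  expect_gt(max(psa$incremental_cost_total), base)
  # one row per draw, parameters alongside outcomes, CSV-ready
  expect_true(all(c("p_nec_usual", "rr_nec", "cost_nec_surgical",
                    "incremental_cost_total", "inc_nec") %in% names(psa)))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(psa, path, row.names = FALSE)
  expect_equal(nrow(utils::read.csv(path)), 120)
})
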