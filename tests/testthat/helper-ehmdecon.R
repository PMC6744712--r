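# Shared fixtures: everything is built in code at test time.

base_model <- function(...) ehmd_model(...)

# independent arithmetic oracle for the EHMD diet cost (mixing rule)
oracle_diet_cost <- function(vol_mother, vol_donor, price_vial, mix_ml,
                             price_donor_l) {
  (vol_mother + vol_donor) / mix_ml * price_vial +
    vol_donor / 1000 * price_donor_l
}

# societal block used wherever the societal machinery is exercised
synthetic_societal <- function() {
  list(cost_cp_lifetime_societal = 921000,
       earnings_loss_per_iq_point = 14500,
       rop_productivity_loss = 150000)
}

base_config_path <- function() {
  system.file("extdata", "base_case.yaml", package = "ehmdecon")
}
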