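# Base-case configuration: cohort decision-tree model of an exclusive human
# milk diet (EHMD) vs usual practice of care for VLBW infants.
# All monetary values are 2016 USD.
#
# The societal block's unit inputs are not published base-case values; the
# figures below are SYNTHETIC placeholders shipped only so the societal
# machinery can be exercised. Replace them with calibrated values before
# drawing societal conclusions.
settings:
  cohort_size: 1000
  discount_rate: 0.03
  price_year: 2016
clinical:
  p_nec_usual: 0.167
  frac_nec_surgical_usual: 0.635
  p_sepsis_usual: 0.303
  p_death_usual: 0.172
  p_bpd_usual: 0.563
  p_rop_usual: 0.090
  rr_nec: 0.31
  rr_sepsis: 0.87
  rr_death: 0.79
  rr_bpd: 0.99
  rr_rop: 0.15
  rr_nec_surgical: 0.1132
  p_sbs_given_surgical_nec: 0.157
  p_cp_base: 0.148
  or_cp_nec: 1.55
  iq_loss_nec: 11
  iq_loss_sepsis: 9
costs:
  vol_mother_ehmd_ml: 1943
  vol_donor_ehmd_ml: 883
  vol_mother_usual_ml: 2102
  vol_formula_usual_ml: 2109
  price_fortifier_vial: 187.50
  vial_ml: 30
  milk_per_vial_ml: 70
  price_donor_milk_per_l: 183
  cost_diet_usual: 226
  cost_baseline_stay: 49660
  cost_nec_surgical: 229431
  cost_nec_medical: 85734
  cost_sepsis: 12413
  cost_bpd: 38966
  cost_rop: 5939
  cost_cp_lifetime_payer: 147268
  price_year: 2016
  societal:
    cost_cp_lifetime_societal: 921000   # synthetic placeholder
    earnings_loss_per_iq_point: 14500   # synthetic placeholder
    rop_productivity_loss: 150000       # synthetic placeholder
scenarios:
  lower_cost:
    clinical:
      p_nec_usual: 0.172
      frac_nec_surgical_usual: 0.688
      p_sepsis_usual: 0.344
      p_death_usual: 0.075
      p_bpd_usual: 0.301
      p_rop_usual: 0.107
      rr_sepsis: 0.63
      rr_bpd: 0.85
  higher_cost:
    clinical:
      rr_nec: 0.41
      rr_rop: 0.58
      rr_death: 0.24
  mortality_rct:
    clinical:
      rr_death: 0.24
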