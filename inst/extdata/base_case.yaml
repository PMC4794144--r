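# Base-case model configuration (GBP 2013/14, NHS Scotland payer perspective).
# Probabilities are proportions, times are days, utilities are EQ-5D index
# values / increments.
baseline_utility: 0.57
therapies:
  capsaicin:
    p_response: 0.5567
    p_discontinue_ae: 0.0
    t_onset_days: 7.5
    u_increment: 0.2284
  pregabalin:
    # base case assumes equal efficacy (non-inferiority); the observed
    # trial response rate is kept for the clinical-efficacy scenario
    p_response: 0.5567
    p_response_observed: 0.5451
    p_discontinue_ae: 0.085
    t_onset_days: 36.0
    u_increment: 0.1989
  last_line:
    p_response: 0.20
    p_discontinue_ae: 0.0
    t_onset_days: 0.0
    u_increment: 0.2284
costs:
  patch_unit_cost: 210.0
  # full-precision value recovered as acquisition-per-treatment (290.43)
  # divided by the patch unit cost; the displayed 1.38 does not reproduce
  # the published per-treatment acquisition cost
  mean_patches_per_treatment: 1.3830
  nurse_hourly_rate: 119.0
  nurse_contact_hours: 0.5
  gloves_cost: 0.06
  anesthesia_cost_per_application: 34.19
  pregabalin_cost_per_tablet: 1.15
  pregabalin_doses_per_day: 2
  lastline_cost_per_tablet: 0.99
  lastline_doses_per_day: 1
  gp_visit_cost: 45.0
  specialist_visit_cost: 125.0
  t_retreat_days: 179.0
discount_rate: 0.035
horizon_years: 2
assessment_days: 56
year_length_days: 365
anesthesia: false
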