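# Base-case model configuration: published inputs of the Italian societal
# cost-effectiveness comparison of early escalation to natalizumab (ESC) vs.
# switching among immunomodulators with late escalation (SWI) in RRMS.
#
# EDSS is discretized to 9 bands: 0..7 plus band 8 = the 8-10 aggregate.
# All per-band vectors run band 0 .. band 8.
#
# Blocks NOT present here (utilities, spms, mortality, adverse_events) are
# filled from the placeholder document at load time and flagged
# provenance = "placeholder".

settings:
  discount_rate: 0.035        # per year, applied to costs and outcomes
  horizon: 50                 # annual cycles (lifetime horizon)
  relapse_cost: 4744          # EUR per relapse event (inflation-adjusted)
  wtp_threshold: 50000        # EUR per QALY gained

cohort:
  start_age: 35.3
  female_fraction: 0.658
  # baseline EDSS distribution (bands 0-8); all mass on bands 1-5
  edss_distribution: [0.0, 0.2561, 0.3719, 0.2070, 0.1018, 0.0632, 0.0, 0.0, 0.0]

relapse_rates:
  # untreated annualized relapse rates by band; RRMS band 0 is not published
  # and defaults to the band-1 value (nearest neighbour, configurable here).
  rrms: [1.7534, 1.7534, 1.7534, 1.6698, 1.7966, 1.3793, 1.5556, 1.5556, 0.1555]
  # SPMS band-1 entry printed as "10.0000", read as footnote marker "1" +
  # value 0.0000 (the plausible alternative, 10.0 relapses/year, is clinically
  # implausible); band 0 defaults to the band-1 value.
  spms: [0.0, 0.0, 0.3147, 0.6020, 0.5146, 0.1604, 0.1387, 0.1041, 0.1041]

treatment_effect:
  arr_multiplier_switching: 0.6574   # ARR multiplier, switching vs untreated
  relapse_rr_esc_vs_swi: 0.46        # relapse rate ratio, escalation vs switching

shift_vectors:
  # annual EDSS-shift probabilities over changes of -1, 0, +1, +2, +3 points;
  # the escalation vector sums to 1.0001 as printed and is renormalized at load.
  support: [-1, 0, 1, 2, 3]
  esc: [0.0236, 0.8727, 0.0849, 0.0189, 0.0000]
  swi: [0.0000, 0.8199, 0.1553, 0.0217, 0.0031]
  # off-treatment RRMS progression; null = use the switching vector
  off_treatment: null

disability_costs:
  # EUR per patient-year by band 0-8 (indirect includes productivity loss and
  # non-healthcare direct costs)
  rrms_direct:   [201, 201, 201, 636, 636, 636, 636, 5708, 5708]
  rrms_indirect: [1143, 1143, 1143, 11847, 11847, 11847, 11847, 28411, 28411]
  spms_direct:   [5331, 5331, 5331, 18894, 18894, 18894, 18894, 9589, 9589]
  spms_indirect: [4096, 4096, 4096, 31559, 31559, 31559, 31559, 64948, 64948]

treatments:
  # ex-factory pack prices and annual monitoring/administration costs (EUR).
  # packs_per_year = doses_per_year(posology) / units_per_pack unless given
  # explicitly; units_per_pack reflects marketed pack sizes and is a model
  # convention (pack contents are not published), overridable here.
  natalizumab:
    pack_price: 1800.00
    posology: q4w
    units_per_pack: 1
    monitoring_year1: 1104.69
    monitoring_subsequent: 421.42
    administration_annual: 589.78
    rebate_fraction: 0
  ifn_beta1a_44:
    pack_price: 1027.75
    posology: tiw
    units_per_pack: 12
    monitoring_year1: 1084.04
    monitoring_subsequent: 399.22
    administration_annual: 0
    rebate_fraction: 0
  ifn_beta1b:
    pack_price: 856.01
    posology: every_other_day
    units_per_pack: 15
    monitoring_year1: 1084.04
    monitoring_subsequent: 399.22
    administration_annual: 0
    rebate_fraction: 0
  glatiramer:
    pack_price: 769.30
    posology: od
    units_per_pack: 28
    monitoring_year1: 932.51
    monitoring_subsequent: 313.18
    administration_annual: 0
    rebate_fraction: 0
  ifn_beta1a_30:
    pack_price: 790.17
    posology: qw
    units_per_pack: 4
    monitoring_year1: 1084.04
    monitoring_subsequent: 399.22
    administration_annual: 0
    rebate_fraction: 0

first_line_mix:
  # first-line treatment distribution; remainder (0.0) to IFN beta-1a 30 mcg
  ifn_beta1a_44: 0.584
  ifn_beta1b: 0.087
  glatiramer: 0.329
  ifn_beta1a_30: 0.0

strategies:
  esc:
    initial_phase: NATALIZUMAB
    escalation_edss_threshold: 0   # escalate at model entry
    stop_edss_threshold: 7         # stop all DMT at EDSS >= 7
  swi:
    initial_phase: FIRST_LINE
    escalation_edss_threshold: 4   # late escalation at EDSS >= 4
    stop_edss_threshold: 7

psa:
  n_iterations: 1000
  se_fraction: 0.10
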