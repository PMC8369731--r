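# Default model configuration: lifetime cost-utility base case for
# trabecular micro-bypass stent + cataract surgery vs cataract surgery alone
# in mild-to-moderate open-angle glaucoma (Italian NHS payer perspective).
# Monetary values are EUR; rates are per year unless noted.

cohort_start_age: 64.7        # years at model entry (mean trial age)
max_age: 110                  # horizon truncation, years
cycle_length: 1               # months per Markov cycle
discount_rate_costs: 0.035    # annual
discount_rate_effects: 0.035  # annual

initial_state_split:          # proportion of the cohort per living state
  mild: 0.5
  moderate: 0.5
  advanced: 0.0
  severe: 0.0

# Visual-field (mean deviation) progression
untreated_vf_decline: 0.0508        # dB lost per month, untreated (stored positive)
decline_reduction_per_mmhg: 0.095   # relative reduction of VF decline per mmHg of IOP lowering
progression_hr_per_mmhg: 0.88       # hazard ratio for disease progression per mmHg
band_widths:                        # dB width of each severity band (Hodapp-Parrish-Anderson)
  mild: 6
  moderate: 6
  advanced: 8

# Baseline (untreated) time-to-progression driving the switch to trabeculectomy,
# lognormal on months. Not directly observable; calibrated against the base-case
# lifetime outcomes (see calibrate_progression()).
nat_progression_lognormal:
  meanlog: 5.46
  sdlog: 0.8

trabeculectomy_iop_reduction: 6.48  # mmHg, replaces the arm effect after the switch
discontinuation_mean_time: 8.6      # months, mean time on topical medication
unmedicated_iop_offset: 7           # mmHg medicated-vs-unmedicated difference
                                    # (already embedded in the IOP schedules; kept for DSA)
half_cycle_correction: false

# Effective IOP reduction vs baseline (mmHg), per model year 1..10 then "10+".
# Trial values at years 1-2, expert-based waning thereafter; medication
# discontinuation is already folded in.
iop_schedule:
  istent:   [7.1, 6.6, 5.7, 5.4, 5.1, 4.8, 4.5, 4.3, 4.0, 3.8, 3.6]
  cataract: [5.5, 4.4, 3.6, 3.3, 3.2, 3.0, 2.8, 2.7, 2.5, 2.4, 2.3]

costs:
  procedure:                 # index intervention, one-time at cycle 0
    istent: 2294.20
    cataract: 994.00
  trabeculectomy: 1969.10    # per switch event
  medications:               # monthly price (EUR) and Italian market share
    - {name: bimatoprost,            price: 20.23, share: 0.156}
    - {name: bimatoprost_timolol,    price: 27.25, share: 0.115}
    - {name: brinzolamide_timolol,   price: 16.88, share: 0.139}
    - {name: dorzolamide_timolol,    price:  7.33, share: 0.164}
    - {name: travoprost_timolol,     price: 18.26, share: 0.066}
    - {name: timolol,                price:  5.70, share: 0.254}
    - {name: tafluprost,             price: 25.94, share: 0.107}
  medication_factor:         # mean concurrent-medication multiplier per arm,
    istent: 0.2138           # reverse-engineered from reported lifetime
    cataract: 0.4276         # medication spend (comparator = 2x stent arm)
  monitoring:
    unit_costs:
      consultation: 20.66
      gonioscopy: 7.75
      vf_test: 16.78
      imaging: 90.00
    incidence:               # expected uses per month, by severity state
      mild:     {consultation: 0.17, gonioscopy: 0.08, vf_test: 0.17, imaging: 0.17}
      moderate: {consultation: 0.25, gonioscopy: 0.08, vf_test: 0.17, imaging: 0.17}
      advanced: {consultation: 0.33, gonioscopy: 0.08, vf_test: 0.25, imaging: 0.33}
      severe:   {consultation: 0.25, gonioscopy: 0.08, vf_test: 0.17, imaging: 0.17}
  adverse_events:            # one-time, applied undiscounted at cycle 0
    unit_costs:
      hyperaemia: 20.66
      stent_obstruction: 1522.00
    incidence:
      istent:   {hyperaemia: 0.008, stent_obstruction: 0.062}
      cataract: {hyperaemia: 0.059, stent_obstruction: 0.0}

utilities:                   # per severity state, per year
  mild: 0.847
  moderate: 0.781
  advanced: 0.704
  severe: 0.594

disutilities:
  trabeculectomy: 0.007           # one-off decrement at the switch event
  medication_ae: 0.101            # decrement while on medication with an AE
  medication_ae_incidence: 0.089  # market-share-weighted AE incidence

psa_settings:
  n_reps: 1000
  seed: 20210817

dsa_settings:
  default_rel_width: 0.20    # +/- fraction when no 95% CI is available
  iop_rel_width: 0.10        # +/- fraction for the trial IOP-reduction schedules
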