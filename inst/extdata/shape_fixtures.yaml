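# Qualitative-shape fixture tolerances for the default BMEC model.
# Encodings of the qualitative OGD/R dynamics the model must reproduce;
# kept in one place so they can be tightened without touching code.
succinate_ogd_rise:
  observable: Succinate
  protocol: ogdr_6_24
  constraint: monotone_increasing
  window: [1, 6]
succinate_reox_oxidation:
  observable: Succinate
  protocol: ogdr_6_24
  constraint: drop_after
  at: 6
  within: 2
  fraction_of_rise: 0.5
ros_reox_peak:
  observable: ROS
  protocol: ogdr_6_24
  constraint: peak_after
  t: 6
ampk_double_peak:
  observable: AMPKp
  protocol: ogdr_6_24
  constraint: two_peaks
  first_window: [0, 6]
  second_window: [10, 14]
  min_prominence: 0.1
p53_rise_return:
  observable: p53
  protocol: ogdr_6_24
  constraint: rise_and_return
  peak_factor: 1.3
  peak_window: [0, 10]
  final_band: [0.8, 1.2]
hif1a_rise_decline:
  observable: HIF1a
  protocol: ogdr_6_24
  constraint: elevated_then_declining
  at: 6
  factor: 1.2
  decline_window: [8, 30]
cytokine_ogd_monotone:
  observable: IL6
  protocols: [ogdr_1_24, ogdr_3_24, ogdr_6_24, ogdr_24_24]
  constraint: endpoint_monotone_across
growth_factor_return:
  observable: Ang2
  protocol: ogdr_6_24
  constraint: pulse_return
  peak_factor: 1.5
  final_band: [0.8, 1.25]
caspase_reversible_short_ogd:
  observable: Casp3
  protocol: ogdr_3_24
  constraint: decline_after_peak
  window_start: 3
  final_max_fraction: 0.85
caspase_committed_long_ogd:
  observable: Casp3
  protocol: ogdr_24_24
  constraint: stays_near_max
  window_start: 24
  final_min_fraction: 0.9
tight_junction_decline:
  observable: ZO1
  protocol: ogdr_6_24
  constraint: final_below
  factor: 0.85
claudin5_decline:
  observable: Claudin5
  protocol: ogdr_6_24
  constraint: final_below
  factor: 0.85
fgf_attenuates_tj_decline:
  observable: ZO1
  protocols: [ogdr_6_24, ogdr_6_24_fgf]
  constraint: endpoint_higher_in_second
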