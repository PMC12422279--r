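# Correlated-random-walk movement parameters for the focal Chilean
# mesocarnivores. Step-length / turning parameters are footprint-chain
# averages from ecologically matched surrogate species; home ranges are
# means of published estimates (Lycalopex pools culpeo + gray fox values:
# mean(3.5, 4.65, 6, 6.5, 9.2, 2) = 5.31 km2).
"Lycalopex spp.":
  mean_step_m: 13.18
  sd_step_m: 17.31
  sd_turn_deg: 26.31
  steps_per_month: 5000
  home_range_km2: 5.31
"Leopardus guigna":
  mean_step_m: 19.03
  sd_step_m: 13.07
  sd_turn_deg: 41.04
  steps_per_month: 3000
  home_range_km2: 4.85   # mean(1.25, 1.5, 11.8)
"Conepatus chinga":
  mean_step_m: 12.77
  sd_step_m: 15.16
  sd_turn_deg: 52.12
  steps_per_month: 4000
  home_range_km2: 1.61   # mean(1.09, 1.63, 1.67, 1.78, 1.9)
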