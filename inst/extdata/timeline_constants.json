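{
  "fertilization_min": 0,
  "sampling_window_min": [265, 400],
  "comma_stage_min": 400,
  "axonal_outgrowth_min": 450,
  "twitching_min": 470,
  "pharyngeal_pumping_min": [760, 780],
  "hatch_min": 800,
  "burst_windows_min": [[210, 285], [285, 345], [365, 400]],
  "birth_gap_min": [345, 365]
}
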