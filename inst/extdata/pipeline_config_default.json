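{
  "filter": {"method": "butterworth", "low_cut": 0.5, "high_cut": 8, "order": 4},
  "segment_length_s": 30,
  "invalid_tolerance": 0,
  "flatline_min_s": 2,
  "zero_run_min_s": 2,
  "detector_id": 5,
  "msq_detectors": [5, 6],
  "msq_shift_s": 1,
  "correlogram_n_peaks": 3,
  "beat_target_len": 100,
  "ectopic_rule": "malik"
}
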