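{
  "5MHZ": {
    "f0_mhz": 5,
    "frac_bw": 0.75,
    "c_mm_us": 1.54,
    "fnum_x": 2,
    "fnum_y": 4,
    "tau_beta": 16,
    "snr_db": 30,
    "fs_mhz": 38.5,
    "lateral_interval_mm": 0.1,
    "frame_rate_hz": 10,
    "modality": "RF",
    "iq_decimation": 1
  },
  "20MHZ": {
    "f0_mhz": 20,
    "frac_bw": 0.4,
    "c_mm_us": 1.54,
    "fnum_x": 2,
    "fnum_y": 4,
    "tau_beta": 5,
    "snr_db": 15,
    "fs_mhz": 128.3,
    "lateral_interval_mm": 0.06,
    "frame_rate_hz": 20,
    "modality": "IQ",
    "iq_decimation": 5
  }
}
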