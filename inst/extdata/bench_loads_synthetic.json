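{
  "comment": "Synthetic bench electrode-load models. The physical fixture circuits are specified only by impedance magnitude at 1 kHz (33.7 kOhm metal microelectrode, 325 kOhm small-tip electrode, each behind ~1 kOhm series resistance); component values below were fitted with fit_interface_model(z, rp_factor = 10).",
  "metal": {
    "r_series_ohm": 1000,
    "r_parallel_ohm": 337000,
    "c_parallel_f": 4.71518648575725e-09,
    "v_limit_v": 2.42,
    "z_1khz_ohm": 33700
  },
  "small_tip": {
    "r_series_ohm": 1000,
    "r_parallel_ohm": 3250000,
    "c_parallel_f": 4.87406572827188e-10,
    "v_limit_v": 2.42,
    "z_1khz_ohm": 325000
  }
}
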