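# Synthetic CHU-9D tariff (additive decrements from 1.0).
# This is NOT a country value set. It is a synthetic stand-in with the
# qualitative shape of published CHU-9D tariffs (zero decrement at level 1,
# decrements increasing with level, pain/sad weighted most heavily,
# worst-state utility 0.315), shipped so the mapping pipeline is runnable
# and testable without external data. Real analyses must supply the
# appropriate country tariff via read_valueset().
version: "1.0"
worried:       [0.0, 0.012, 0.028, 0.051, 0.079]
sad:           [0.0, 0.015, 0.034, 0.062, 0.098]
pain:          [0.0, 0.016, 0.036, 0.066, 0.103]
tired:         [0.0, 0.010, 0.024, 0.043, 0.068]
annoyed:       [0.0, 0.009, 0.022, 0.040, 0.062]
schoolwork:    [0.0, 0.011, 0.026, 0.047, 0.072]
sleep:         [0.0, 0.010, 0.023, 0.042, 0.065]
daily_routine: [0.0, 0.011, 0.025, 0.046, 0.071]
activities:    [0.0, 0.010, 0.024, 0.044, 0.067]
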