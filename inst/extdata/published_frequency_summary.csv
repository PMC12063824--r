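frequency,avg_mean,avg_min,avg_max,raw_mean,raw_min,raw_max
quarterly,69.0,24.9,174.6,69.7,8.2,305.6
monthly,69.5,17.2,260.4,69.7,8.2,305.6
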