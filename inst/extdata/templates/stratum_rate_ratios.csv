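stratum,age_band_start,age_band_end,ratio
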