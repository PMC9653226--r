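{"edit_rate":0.05,"scarring_multipliers":[3,1],"silencing_rate":0,"window_start":0,"window_end":16,"parameterization":"multiplier"}
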