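name	value
loop_extrapolation	1.079
duplex_init	4.09
max_interior	30
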