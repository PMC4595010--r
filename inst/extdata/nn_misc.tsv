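param	value
ml_init	9.3
ml_branch	-0.9
ml_unpaired	0.0
ninio_per_nt	0.6
ninio_max	3.0
terminal_au	0.5
duplex_init	4.1
rt	0.61632
max_loop	30
loop_extrapolation	1.75
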