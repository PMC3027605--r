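variable	printed_p
gender	0,185
location	0,027
t_status	0,01
n_status	0,01
stage	0
differentiation	0,3
msi	0,124
adjuvant	0,014
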