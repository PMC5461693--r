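# property: duplex_disrupt_energy
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	1.0910
AC	1.2300
AG	0.2900
AT	0.9960
CA	2.0840
CC	0.6750
CG	0.5090
CT	0.2900
GA	1.4070
GC	1.0630
GG	0.6750
GT	1.2300
TA	1.5860
TC	1.4070
TG	2.0840
TT	1.0910
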