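# property: shift
# k: 2
# units: angstrom
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-0.0120
AC	0.4630
AG	0.2120
AT	0.1210
CA	0.2020
CC	0.2600
CG	0.3590
CT	0.2120
GA	0.1540
GC	0.9280
GG	0.2600
GT	0.4630
TA	0.2750
TC	0.1540
TG	0.2020
TT	-0.0120
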