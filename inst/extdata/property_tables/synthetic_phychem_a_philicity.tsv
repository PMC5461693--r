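# property: a_philicity
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-0.1200
AC	0.1690
AG	-0.1070
AT	0.3440
CA	0.0940
CC	-0.0360
CG	-0.0460
CT	-0.1070
GA	-0.2000
GC	-0.0440
GG	-0.0360
GT	0.1690
TA	-0.3160
TC	-0.2000
TG	0.0940
TT	-0.1200
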