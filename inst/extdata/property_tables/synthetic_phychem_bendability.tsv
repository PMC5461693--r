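# property: bendability
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-0.0340
AC	0.0990
AG	0.2130
AT	-0.1940
CA	-0.0980
CC	0.0440
CG	-0.1200
CT	0.2130
GA	0.0620
GC	0.0730
GG	0.0440
GT	0.0990
TA	-0.0370
TC	0.0620
TG	-0.0980
TT	-0.0340
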