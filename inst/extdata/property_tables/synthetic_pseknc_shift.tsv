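# property: shift
# k: 2
# units: angstrom
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	0.0010
AC	0.2190
AG	0.0160
AT	0.1710
CA	0.2300
CC	-0.2270
CG	0.3740
CT	0.0160
GA	0.1850
GC	0.2470
GG	-0.2270
GT	0.2190
TA	-0.0040
TC	0.1850
TG	0.2300
TT	0.0010
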