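# property: slide
# k: 2
# units: angstrom
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	0.0970
AC	-0.1510
AG	0.1510
AT	0.2440
CA	-0.0630
CC	-1.0640
CG	0.1480
CT	0.1510
GA	0.6260
GC	-0.5420
GG	-1.0640
GT	-0.1510
TA	0.0230
TC	0.6260
TG	-0.0630
TT	0.0970
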