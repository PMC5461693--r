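# property: slide
# k: 2
# units: angstrom
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-0.6890
AC	-0.0440
AG	-0.3610
AT	0.1260
CA	0.2230
CC	0.3850
CG	0.6870
CT	-0.3610
GA	-0.2470
GC	-0.4780
GG	0.3850
GT	-0.0440
TA	-0.1510
TC	-0.2470
TG	0.2230
TT	-0.6890
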