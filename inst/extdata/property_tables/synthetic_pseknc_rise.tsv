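# property: rise
# k: 2
# units: angstrom
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	3.2810
AC	3.4710
AG	3.4460
AT	3.2230
CA	3.1990
CC	3.1990
CG	3.3100
CT	3.4460
GA	3.5600
GC	3.4210
GG	3.1990
GT	3.4710
TA	3.2860
TC	3.5600
TG	3.1990
TT	3.2810
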