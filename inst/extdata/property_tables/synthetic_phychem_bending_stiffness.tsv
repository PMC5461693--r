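# property: bending_stiffness
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	94.2630
AC	79.7340
AG	107.1650
AT	59.9230
CA	90.3690
CC	54.9400
CG	90.1470
CT	107.1650
GA	45.6560
GC	61.3280
GG	54.9400
GT	79.7340
TA	68.7790
TC	45.6560
TG	90.3690
TT	94.2630
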