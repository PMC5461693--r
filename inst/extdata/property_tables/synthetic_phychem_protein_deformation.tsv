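# property: protein_deformation
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	3.2790
AC	2.4360
AG	2.4790
AT	2.3410
CA	2.2200
CC	3.1500
CG	3.0640
CT	2.4790
GA	2.6250
GC	3.0220
GG	3.1500
GT	2.4360
TA	4.3590
TC	2.6250
TG	2.2200
TT	3.2790
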