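# property: b_dna_twist
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	34.3780
AC	35.0290
AG	34.2630
AT	33.9770
CA	40.3520
CC	38.4640
CG	37.1160
CT	34.2630
GA	38.1930
GC	34.9360
GG	38.4640
GT	35.0290
TA	38.9100
TC	38.1930
TG	40.3520
TT	34.3780
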