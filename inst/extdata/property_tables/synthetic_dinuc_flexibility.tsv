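# property: flexibility
# k: 2
# units: arbitrary
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	3.5500
AC	11.0970
AG	7.0990
AT	5.5500
CA	9.3160
CC	13.3530
CG	11.3190
CT	7.0990
GA	9.2320
GC	8.3590
GG	13.3530
GT	11.0970
TA	11.2860
TC	9.2320
TG	9.3160
TT	3.5500
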