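# property: denaturation
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	87.7150
AC	81.9990
AG	91.0730
AT	106.8470
CA	95.1030
CC	76.7010
CG	97.0880
CT	91.0730
GA	80.5190
GC	83.5310
GG	76.7010
GT	81.9990
TA	93.6330
TC	80.5190
TG	95.1030
TT	87.7150
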