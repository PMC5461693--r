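# property: twist
# k: 2
# units: degrees
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	35.2640
AC	36.2640
AG	34.3880
AT	39.2290
CA	35.0540
CC	36.4010
CG	37.2640
CT	34.3880
GA	36.1420
GC	31.9780
GG	36.4010
GT	36.2640
TA	33.8280
TC	36.1420
TG	35.0540
TT	35.2640
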