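# property: twist
# k: 2
# units: degrees
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	30.8120
AC	35.1250
AG	34.9110
AT	41.0700
CA	33.0070
CC	39.0820
CG	38.9470
CT	34.9110
GA	30.7390
GC	32.1040
GG	39.0820
GT	35.1250
TA	37.9810
TC	30.7390
TG	33.0070
TT	30.8120
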