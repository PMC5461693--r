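# property: roll
# k: 2
# units: degrees
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-0.2320
AC	-1.9250
AG	5.3110
AT	7.9920
CA	4.7380
CC	2.8550
CG	-4.3360
CT	5.3110
GA	7.1710
GC	-2.6710
GG	2.8550
GT	-1.9250
TA	4.1890
TC	7.1710
TG	4.7380
TT	-0.2320
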