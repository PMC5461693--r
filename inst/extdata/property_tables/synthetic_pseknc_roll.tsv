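# property: roll
# k: 2
# units: degrees
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	0.3740
AC	4.1440
AG	4.4530
AT	1.2250
CA	9.2310
CC	2.9530
CG	3.7440
CT	4.4530
GA	1.7580
GC	1.0880
GG	2.9530
GT	4.1440
TA	-4.8790
TC	1.7580
TG	9.2310
TT	0.3740
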