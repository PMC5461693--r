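# property: z_dna
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	2.9050
AC	3.4080
AG	1.9370
AT	4.6840
CA	2.7940
CC	3.7260
CG	2.7800
CT	1.9370
GA	1.9600
GC	3.1180
GG	3.7260
GT	3.4080
TA	2.7360
TC	1.9600
TG	2.7940
TT	2.9050
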