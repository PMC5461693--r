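# property: duplex_free_energy
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-1.0740
AC	-0.7950
AG	-1.5110
AT	-1.5350
CA	-0.9220
CC	-1.6480
CG	-1.6650
CT	-1.5110
GA	-1.6050
GC	-1.5310
GG	-1.6480
GT	-0.7950
TA	-0.9930
TC	-1.6050
TG	-0.9220
TT	-1.0740
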