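# property: base_stacking
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-10.6870
AC	-6.8730
AG	-6.8030
AT	-6.0260
CA	-11.1650
CC	-5.5560
CG	-3.9150
CT	-6.8030
GA	-8.7660
GC	-9.6320
GG	-5.5560
GT	-6.8730
TA	-8.0070
TC	-8.7660
TG	-11.1650
TT	-10.6870
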