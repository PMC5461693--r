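# property: tilt
# k: 2
# units: degrees
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	0.0660
AC	-0.3030
AG	1.5160
AT	1.5500
CA	0.4190
CC	-1.1130
CG	0.9750
CT	1.5160
GA	-1.2450
GC	0.4680
GG	-1.1130
GT	-0.3030
TA	1.7170
TC	-1.2450
TG	0.4190
TT	0.0660
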