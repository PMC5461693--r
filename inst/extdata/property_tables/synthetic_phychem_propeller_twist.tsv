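# property: propeller_twist
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	-15.6340
AC	-12.2660
AG	-12.8090
AT	-13.2620
CA	-11.7110
CC	-9.5650
CG	-11.1820
CT	-12.8090
GA	-15.0580
GC	-9.4200
GG	-9.5650
GT	-12.2660
TA	-10.9530
TC	-15.0580
TG	-11.7110
TT	-15.6340
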