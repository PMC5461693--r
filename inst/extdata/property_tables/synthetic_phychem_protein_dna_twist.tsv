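# property: protein_dna_twist
# k: 2
# units: mixed
# source: SYNTHETIC representative scale generated for this package;
#   NOT transcribed from the literature. Magnitudes and strand symmetry
#   are realistic; individual values are placeholders.
AA	34.4220
AC	35.7890
AG	36.0410
AT	32.7680
CA	35.7210
CC	35.3080
CG	34.2320
CT	36.0410
GA	31.6850
GC	32.3380
GG	35.3080
GT	35.7890
TA	32.6830
TC	31.6850
TG	35.7210
TT	34.4220
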