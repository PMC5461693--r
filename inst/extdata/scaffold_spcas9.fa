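>spcas9_scaffold default SpCas9 sgRNA scaffold (tracrRNA-derived constant region), DNA alphabet; package default, configurable
GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC
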