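# property: tetra_flexibility
# k: 4
# units: arbitrary
# source: SYNTHETIC stand-in table generated for this package;
#   NOT transcribed from the literature.
# derived as the sum of the synthetic dinucleotide flexibility steps
AAAA	10.6500
AAAC	18.1970
AAAG	14.1990
AAAT	12.6500
AACA	23.9630
AACC	28.0000
AACG	25.9660
AACT	21.7460
AAGA	19.8810
AAGC	19.0080
AAGG	24.0020
AAGT	21.7460
AATA	20.3860
AATC	18.3320
AATG	18.4160
AATT	12.6500
ACAA	23.9630
ACAC	31.5100
ACAG	27.5120
ACAT	25.9630
ACCA	33.7660
ACCC	37.8030
ACCG	35.7690
ACCT	31.5490
ACGA	31.6480
ACGC	30.7750
ACGG	35.7690
ACGT	33.5130
ACTA	29.4820
ACTC	27.4280
ACTG	27.5120
ACTT	21.7460
AGAA	19.8810
AGAC	27.4280
AGAG	23.4300
AGAT	21.8810
AGCA	24.7740
AGCC	28.8110
AGCG	26.7770
AGCT	22.5570
AGGA	29.6840
AGGC	28.8110
AGGG	33.8050
AGGT	31.5490
AGTA	29.4820
AGTC	27.4280
AGTG	27.5120
AGTT	21.7460
ATAA	20.3860
ATAC	27.9330
ATAG	23.9350
ATAT	22.3860
ATCA	24.0980
ATCC	28.1350
ATCG	26.1010
ATCT	21.8810
ATGA	24.0980
ATGC	23.2250
ATGG	28.2190
ATGT	25.9630
ATTA	20.3860
ATTC	18.3320
ATTG	18.4160
ATTT	12.6500
CAAA	16.4160
CAAC	23.9630
CAAG	19.9650
CAAT	18.4160
CACA	29.7290
CACC	33.7660
CACG	31.7320
CACT	27.5120
CAGA	25.6470
CAGC	24.7740
CAGG	29.7680
CAGT	27.5120
CATA	26.1520
CATC	24.0980
CATG	24.1820
CATT	18.4160
CCAA	26.2190
CCAC	33.7660
CCAG	29.7680
CCAT	28.2190
CCCA	36.0220
CCCC	40.0590
CCCG	38.0250
CCCT	33.8050
CCGA	33.9040
CCGC	33.0310
CCGG	38.0250
CCGT	35.7690
CCTA	31.7380
CCTC	29.6840
CCTG	29.7680
CCTT	24.0020
CGAA	24.1010
CGAC	31.6480
CGAG	27.6500
CGAT	26.1010
CGCA	28.9940
CGCC	33.0310
CGCG	30.9970
CGCT	26.7770
CGGA	33.9040
CGGC	33.0310
CGGG	38.0250
CGGT	35.7690
CGTA	33.7020
CGTC	31.6480
CGTG	31.7320
CGTT	25.9660
CTAA	21.9350
CTAC	29.4820
CTAG	25.4840
CTAT	23.9350
CTCA	25.6470
CTCC	29.6840
CTCG	27.6500
CTCT	23.4300
CTGA	25.6470
CTGC	24.7740
CTGG	29.7680
CTGT	27.5120
CTTA	21.9350
CTTC	19.8810
CTTG	19.9650
CTTT	14.1990
GAAA	16.3320
GAAC	23.8790
GAAG	19.8810
GAAT	18.3320
GACA	29.6450
GACC	33.6820
GACG	31.6480
GACT	27.4280
GAGA	25.5630
GAGC	24.6900
GAGG	29.6840
GAGT	27.4280
GATA	26.0680
GATC	24.0140
GATG	24.0980
GATT	18.3320
GCAA	21.2250
GCAC	28.7720
GCAG	24.7740
GCAT	23.2250
GCCA	31.0280
GCCC	35.0650
GCCG	33.0310
GCCT	28.8110
GCGA	28.9100
GCGC	28.0370
GCGG	33.0310
GCGT	30.7750
GCTA	26.7440
GCTC	24.6900
GCTG	24.7740
GCTT	19.0080
GGAA	26.1350
GGAC	33.6820
GGAG	29.6840
GGAT	28.1350
GGCA	31.0280
GGCC	35.0650
GGCG	33.0310
GGCT	28.8110
GGGA	35.9380
GGGC	35.0650
GGGG	40.0590
GGGT	37.8030
GGTA	35.7360
GGTC	33.6820
GGTG	33.7660
GGTT	28.0000
GTAA	25.9330
GTAC	33.4800
GTAG	29.4820
GTAT	27.9330
GTCA	29.6450
GTCC	33.6820
GTCG	31.6480
GTCT	27.4280
GTGA	29.6450
GTGC	28.7720
GTGG	33.7660
GTGT	31.5100
GTTA	25.9330
GTTC	23.8790
GTTG	23.9630
GTTT	18.1970
TAAA	18.3860
TAAC	25.9330
TAAG	21.9350
TAAT	20.3860
TACA	31.6990
TACC	35.7360
TACG	33.7020
TACT	29.4820
TAGA	27.6170
TAGC	26.7440
TAGG	31.7380
TAGT	29.4820
TATA	28.1220
TATC	26.0680
TATG	26.1520
TATT	20.3860
TCAA	22.0980
TCAC	29.6450
TCAG	25.6470
TCAT	24.0980
TCCA	31.9010
TCCC	35.9380
TCCG	33.9040
TCCT	29.6840
TCGA	29.7830
TCGC	28.9100
TCGG	33.9040
TCGT	31.6480
TCTA	27.6170
TCTC	25.5630
TCTG	25.6470
TCTT	19.8810
TGAA	22.0980
TGAC	29.6450
TGAG	25.6470
TGAT	24.0980
TGCA	26.9910
TGCC	31.0280
TGCG	28.9940
TGCT	24.7740
TGGA	31.9010
TGGC	31.0280
TGGG	36.0220
TGGT	33.7660
TGTA	31.6990
TGTC	29.6450
TGTG	29.7290
TGTT	23.9630
TTAA	18.3860
TTAC	25.9330
TTAG	21.9350
TTAT	20.3860
TTCA	22.0980
TTCC	26.1350
TTCG	24.1010
TTCT	19.8810
TTGA	22.0980
TTGC	21.2250
TTGG	26.2190
TTGT	23.9630
TTTA	18.3860
TTTC	16.3320
TTTG	16.4160
TTTT	10.6500
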