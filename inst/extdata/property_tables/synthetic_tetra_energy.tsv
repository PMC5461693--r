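# property: tetra_energy
# k: 4
# units: kcal/mol
# source: SYNTHETIC stand-in table generated for this package;
#   NOT transcribed from the literature.
# derived as the sum of nearest-neighbor dG37 over the three steps
AAAA	-3.0000
AAAC	-3.4400
AAAG	-3.2800
AAAT	-2.8800
AACA	-3.8900
AACC	-4.2800
AACG	-4.6100
AACT	-3.7200
AAGA	-3.5800
AAGC	-4.5200
AAGG	-4.1200
AAGT	-3.7200
AATA	-2.4600
AATC	-3.1800
AATG	-3.3300
AATT	-2.8800
ACAA	-3.8900
ACAC	-4.3300
ACAG	-4.1700
ACAT	-3.7700
ACCA	-4.7300
ACCC	-5.1200
ACCG	-5.4500
ACCT	-4.5600
ACGA	-4.9100
ACGC	-5.8500
ACGG	-5.4500
ACGT	-5.0500
ACTA	-3.3000
ACTC	-4.0200
ACTG	-4.1700
ACTT	-3.7200
AGAA	-3.5800
AGAC	-4.0200
AGAG	-3.8600
AGAT	-3.4600
AGCA	-4.9700
AGCC	-5.3600
AGCG	-5.6900
AGCT	-4.8000
AGGA	-4.4200
AGGC	-5.3600
AGGG	-4.9600
AGGT	-4.5600
AGTA	-3.3000
AGTC	-4.0200
AGTG	-4.1700
AGTT	-3.7200
ATAA	-2.4600
ATAC	-2.9000
ATAG	-2.7400
ATAT	-2.3400
ATCA	-3.6300
ATCC	-4.0200
ATCG	-4.3500
ATCT	-3.4600
ATGA	-3.6300
ATGC	-4.5700
ATGG	-4.1700
ATGT	-3.7700
ATTA	-2.4600
ATTC	-3.1800
ATTG	-3.3300
ATTT	-2.8800
CAAA	-3.4500
CAAC	-3.8900
CAAG	-3.7300
CAAT	-3.3300
CACA	-4.3400
CACC	-4.7300
CACG	-5.0600
CACT	-4.1700
CAGA	-4.0300
CAGC	-4.9700
CAGG	-4.5700
CAGT	-4.1700
CATA	-2.9100
CATC	-3.6300
CATG	-3.7800
CATT	-3.3300
CCAA	-4.2900
CCAC	-4.7300
CCAG	-4.5700
CCAT	-4.1700
CCCA	-5.1300
CCCC	-5.5200
CCCG	-5.8500
CCCT	-4.9600
CCGA	-5.3100
CCGC	-6.2500
CCGG	-5.8500
CCGT	-5.4500
CCTA	-3.7000
CCTC	-4.4200
CCTG	-4.5700
CCTT	-4.1200
CGAA	-4.4700
CGAC	-4.9100
CGAG	-4.7500
CGAT	-4.3500
CGCA	-5.8600
CGCC	-6.2500
CGCG	-6.5800
CGCT	-5.6900
CGGA	-5.3100
CGGC	-6.2500
CGGG	-5.8500
CGGT	-5.4500
CGTA	-4.1900
CGTC	-4.9100
CGTG	-5.0600
CGTT	-4.6100
CTAA	-2.8600
CTAC	-3.3000
CTAG	-3.1400
CTAT	-2.7400
CTCA	-4.0300
CTCC	-4.4200
CTCG	-4.7500
CTCT	-3.8600
CTGA	-4.0300
CTGC	-4.9700
CTGG	-4.5700
CTGT	-4.1700
CTTA	-2.8600
CTTC	-3.5800
CTTG	-3.7300
CTTT	-3.2800
GAAA	-3.3000
GAAC	-3.7400
GAAG	-3.5800
GAAT	-3.1800
GACA	-4.1900
GACC	-4.5800
GACG	-4.9100
GACT	-4.0200
GAGA	-3.8800
GAGC	-4.8200
GAGG	-4.4200
GAGT	-4.0200
GATA	-2.7600
GATC	-3.4800
GATG	-3.6300
GATT	-3.1800
GCAA	-4.6900
GCAC	-5.1300
GCAG	-4.9700
GCAT	-4.5700
GCCA	-5.5300
GCCC	-5.9200
GCCG	-6.2500
GCCT	-5.3600
GCGA	-5.7100
GCGC	-6.6500
GCGG	-6.2500
GCGT	-5.8500
GCTA	-4.1000
GCTC	-4.8200
GCTG	-4.9700
GCTT	-4.5200
GGAA	-4.1400
GGAC	-4.5800
GGAG	-4.4200
GGAT	-4.0200
GGCA	-5.5300
GGCC	-5.9200
GGCG	-6.2500
GGCT	-5.3600
GGGA	-4.9800
GGGC	-5.9200
GGGG	-5.5200
GGGT	-5.1200
GGTA	-3.8600
GGTC	-4.5800
GGTG	-4.7300
GGTT	-4.2800
GTAA	-3.0200
GTAC	-3.4600
GTAG	-3.3000
GTAT	-2.9000
GTCA	-4.1900
GTCC	-4.5800
GTCG	-4.9100
GTCT	-4.0200
GTGA	-4.1900
GTGC	-5.1300
GTGG	-4.7300
GTGT	-4.3300
GTTA	-3.0200
GTTC	-3.7400
GTTG	-3.8900
GTTT	-3.4400
TAAA	-2.5800
TAAC	-3.0200
TAAG	-2.8600
TAAT	-2.4600
TACA	-3.4700
TACC	-3.8600
TACG	-4.1900
TACT	-3.3000
TAGA	-3.1600
TAGC	-4.1000
TAGG	-3.7000
TAGT	-3.3000
TATA	-2.0400
TATC	-2.7600
TATG	-2.9100
TATT	-2.4600
TCAA	-3.7500
TCAC	-4.1900
TCAG	-4.0300
TCAT	-3.6300
TCCA	-4.5900
TCCC	-4.9800
TCCG	-5.3100
TCCT	-4.4200
TCGA	-4.7700
TCGC	-5.7100
TCGG	-5.3100
TCGT	-4.9100
TCTA	-3.1600
TCTC	-3.8800
TCTG	-4.0300
TCTT	-3.5800
TGAA	-3.7500
TGAC	-4.1900
TGAG	-4.0300
TGAT	-3.6300
TGCA	-5.1400
TGCC	-5.5300
TGCG	-5.8600
TGCT	-4.9700
TGGA	-4.5900
TGGC	-5.5300
TGGG	-5.1300
TGGT	-4.7300
TGTA	-3.4700
TGTC	-4.1900
TGTG	-4.3400
TGTT	-3.8900
TTAA	-2.5800
TTAC	-3.0200
TTAG	-2.8600
TTAT	-2.4600
TTCA	-3.7500
TTCC	-4.1400
TTCG	-4.4700
TTCT	-3.5800
TTGA	-3.7500
TTGC	-4.6900
TTGG	-4.2900
TTGT	-3.8900
TTTA	-2.5800
TTTC	-3.3000
TTTG	-3.4500
TTTT	-3.0000
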