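species,locus_class,direction,name,sequence
Ascarosepion bandense,autosome,forward,Abandense_qPCR_auto_F,GGTGTTGTTCGCTCAGTTATC
Ascarosepion bandense,autosome,reverse,Abandense_qPCR_auto_R,GTGTTCATGTCGCCATCTTATC
Ascarosepion bandense,sex,forward,Abandense_qPCR_sex_F,GGCCGTCCTCTACTTGTAATG
Ascarosepion bandense,sex,reverse,Abandense_qPCR_sex_R,AGTAGCTGTGTGGTTGAGAAG
Octopus bimaculoides,autosome,forward,Obimaculoides_qPCR_auto_F,TTGTTTGGACCTTGGGCTTATAG
Octopus bimaculoides,autosome,reverse,Obimaculoides_qPCR_auto_R,CTGTCATGAACCCTGGTGTATTC
Octopus bimaculoides,sex,forward,Obimaculoides_qPCR_sex_F,CCTCACCACTGGATGCAATTAAG
Octopus bimaculoides,sex,reverse,Obimaculoides_qPCR_sex_R,GCCAATCCGTCCAACCTATAC
Sepia officinalis,autosome,forward,Sofficinalis_qPCR_auto_F,TTTGCCACTGTGTCCCTTTATAC
Sepia officinalis,autosome,reverse,Sofficinalis_qPCR_auto_R,ACACACACAGGCTGCTTATTG
Sepia officinalis,sex,forward,Sofficinalis_qPCR_sex_F,TTTCAACCCATCTGCGTCTATAG
Sepia officinalis,sex,reverse,Sofficinalis_qPCR_sex_R,ACTCCTCTCGTTGCATGATTAC
Euprymna berryi,autosome,forward,Eberryi_qPCR_auto_F,CTTTCGCCACGCCTGATATAC
Euprymna berryi,autosome,reverse,Eberryi_qPCR_auto_R,CAGCAGCTTCTTTCCCAGATAAG
Euprymna berryi,sex,forward,Eberryi_qPCR_sex_F,CTGCCCAGCGAATTGTTTATTG
Euprymna berryi,sex,reverse,Eberryi_qPCR_sex_R,TCCGGCGTCTAGGGATTTAG
Doryteuthis pealeii,autosome,forward,Dpealeii_qPCR_auto_F,CACTTCAGCCCGATGGAATAAG
Doryteuthis pealeii,autosome,reverse,Dpealeii_qPCR_auto_R,CTTTGTAAATGCCGCACCTATATC
Doryteuthis pealeii,sex,forward,Dpealeii_qPCR_sex_F,GGAGTCTGAGGTCCGAGATATAG
Doryteuthis pealeii,sex,reverse,Dpealeii_qPCR_sex_R,GCCGAGACCACAAACAATAAC
Illex illecebrosus,autosome,forward,Illex_qPCR_auto_F,AAAACTCCCGACGTCTTGAA
Illex illecebrosus,autosome,reverse,Illex_qPCR_auto_R,GGCCATCCTGGTAGACAAGA
Illex illecebrosus,sex,forward,Illex_qPCR_sex_F,AATCACCCCAACCAGATGAA
Illex illecebrosus,sex,reverse,Illex_qPCR_sex_R,CTCCTGGACCTGGAATGAAA
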