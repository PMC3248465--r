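>cyp19a_promoter_synthetic amplicon (synthetic sequence; 7 CpG loci at study TSS-relative positions)
TTAAGCAAGCGACAAAAAACATAATCACCTGTTATGCAGAGCAAGGAGCTATTACAGGGA
AGACACCACAATCTTAGAGAAACAGTTTAATAATTGATCCTCAAGACAACCACTTATTTT
TAGCATTGAGTATGGGATATGCCAGGGTCAAACTAACATTAGTAGAAAGTTCACATAGAG
AAGTAATAACCCCATATCAATTTGACTGCATTTGAAAAGACCTATTAGATCAAGCACCAA
GGACATAATCAACACACAAGCAGTAAAAGCTGGAAGGGCTGTTGCTAAGATCCACACTGC
CCTCCATCACAATTCCAGAGCCATCCCACTCATAATTCTCATTGCAGCCTAAAACTTGGG
AGCAGGTGCCTCACAAAATATTGCCGCTATCCGGGCAGTCCATACAGCGTCAGCAACACT
GCAGAACCGTAACAGTCACATTATATGCCGACAGCAAGAGGCATCAGAACTAAATTTGGG
AATGAAGAGTAACCCAATTCGCTGATTCTCAAGTGAACTT
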