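>orit_synthetic planted inverted repeats: stems 8 and 10, loops 4
GTCCCAGCCCGGCTAGTAACGGTAGATTATCGATGTAGCGTCAAGGCCACCCATCGCTTG
TCGTCCGGCCTACCGGACGAACGTAACAGGCCTCGTTCAAAGCCGAATCAACTTGGAAGT
GGCATGCAGCCATCGCTGCATGCCCTCACAGGTTCATGCTGCAGGCTGGGTGCCGCTTAC
ACACGCTAAGACAAAGACTTGCGC
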