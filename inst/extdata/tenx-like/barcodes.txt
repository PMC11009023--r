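CCGGTTTCCCGCTGCA
TTGTGCCTGATCGGAG
CCGCTTATGGAAAAAT
ATCACGCCCAGAGTAG
TTGGCCCCACCCGGAT
CCCTGAGTATTCTCAT
GTGCCTGGAAAAGGAA
GCCGTGTAAAGAACTG
CCGTCGCCAGGGGTGG
CTTTCTTGACCTTAGC
GCAGGCCAACGAACGT
AGCGCTAAGGTCAGTA
TCATAGCGGAGAGAAA
TAGCCCGACCCTATCA
CAACCCCTGCATTAAA
GACATCCAAGCAGAGC
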