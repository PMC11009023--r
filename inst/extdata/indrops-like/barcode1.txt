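TATTACGA
AGTTGGGTG
GTACATTTTA
GCTTAACCCGC
GAAGTCATTCTG
GCGTTAAA
CCACCGTGG
GAGACGCATC
CGCGATCTGCC
GCTGCCAGACTG
CTAACTCT
ACTATGATG
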