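CGCTGTGA
TCGCGTCC
TATTCATC
TCGCGCGT
TGTATGTG
ATTGAAAA
GGTCTTCA
ACTACATG
AGTCGAGG
CTCGGTTT
TGCCAGGT
CAGGATGG
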