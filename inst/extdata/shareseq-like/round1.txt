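CGAGGTAG
TTACGACG
CGTTGCGA
GGACCTAA
AGATGACT
CTATAAGT
ACCCCTCT
GGAGATGA
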