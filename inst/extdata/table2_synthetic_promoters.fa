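>SHOX|tss=1000|strand=+
CCCCCCCCCCCCGAGGTCGCCGCGTATAAATAGTGAGACCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC
>GTPBP6|tss=1000|strand=+
CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCATCACGAGCACGTGATGAGGAGCGGCCCCCCCCCCCC
>ASMT|tss=1000|strand=+
CCCCCCCCCCCCCCCCCCCCCCCCCCCGGTGACCTTTTGTGCCCAGAATAGGTCCCCCCCCCCCCCCCCC
>ZFY|tss=1000|strand=+
CGGCGGAGGGGGCCCAACTACCATCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC
>CDY2A|tss=1000|strand=+
CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCAGAATGTTCCATATAATCGTCATAGCCCCCCCCCCCC
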