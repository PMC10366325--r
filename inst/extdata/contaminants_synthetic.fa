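>rRNA_synthetic_1 class=rRNA
UAGAAUAGGCUUUAUUACAGUCUGAUGAAAAAGGAGAUUUUCGCCGACCCGUGUCGACUACUCAAUAAAGGCCUGUAUAAUACAUACCGGUAUCCAAUGCACAAAGUUGUUACUAAUUUCG
>rRNA_synthetic_2 class=rRNA
CCUCCUGGUAGAUGGUCUGAGAAACGUAAUACCCGUGUUCGAGGGAGGUCCUUCAAAAAACACUUGAGAGUCGAAGAGCUUCCCUUACUAGUCUACGAAUUUAAAUU
>tRNA_synthetic_1 class=tRNA
AUUUUCCCAAACAGAUAAUCGUACAAGGAAAUGAGCCUGGGAGUGCAGUACUCUUCCUGAGAGGCAUCCCGAAUAG
>tRNA_synthetic_2 class=tRNA
UCUGCGUUAUCCUAAAAAGGAAAGGCAGGAGACCUCACGACGAAACAAGUCCUCAGGAGCCGUCCCGAAGCCGU
>snoRNA_synthetic_1 class=snoRNA
CGUAUGGUUUGUUUGGGCGGGAAAAAACAGAGUCGUCACCUAUUUUACACGAGGAAACCUACAGGGUAGGACCUUCUGGUAAUACCCUAGGAUCGGAC
>snRNA_synthetic_1 class=snRNA
GAGGCUGCCCCCCAGCGUCAUAGCGGCGGAGAUAAGAGAGUAUGAAAAGGAAUAGAACUCGUAGCGGUUCGCUAUUACAGGCCAUGGAGAGUCAUUUCACGCUAAA
>YRNA_synthetic_1 class=YRNA
CACAAAGAAACAACCAGUCAGGCUACGAGGUGGGCGAUCUGCAAGUAUUAUUUCGUUGCCCGUGCUACCUGGGCUGAAUGUCACAGGCUCGGAUGA
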