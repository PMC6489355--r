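>tRNA_synthetic example pre-tRNA spacer unit (synthetic stand-in; the platform's tRNA is not published)
AACAAAGCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGACCCGGGTTC
GATTCCCGGCTGGTGCA
>scaffold_synthetic example sgRNA scaffold (synthetic stand-in)
GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGT
GGCACCGAGTCGGTGC
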