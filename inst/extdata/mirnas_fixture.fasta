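>hsa-miR-3074-5p mature
GUUCCUGCUGAACUGAGCCAG
>hsa-miR-3131 mature
UCGAGGACUGGUGGAAGGGCCUU
>hsa-miR-3170 mature
CUGGGGUUCUGAGACAGACAGU
>hsa-miR-3614-3p mature
UAGCCUUCAGAUCUUGGUGUUUU
>hsa-miR-3616-3p mature
CGAGGGCAUUUCAUGAUGCAGGC
>hsa-miR-3616-5p mature
AUGAAGUGCACUCAUGAUAUGU
>hsa-miR-449b-5p mature
AGGCAGUGUAUUGUUAGCUGGC
>hsa-miR-616-3p mature
AGUCAUUGGAGGGUUUGAGCAG
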