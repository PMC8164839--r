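>refA_synthetic
MSTAVLRARGQGAKDE-LLNQ
>homologB_synthetic
MSSAVLRARGQGSKDE-LINQ
>homologC_synthetic
MTTAVLRARFQGAKDEELLNQ
>homologD_synthetic
MSTAVLKARGQGAKDE-LLDQ
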