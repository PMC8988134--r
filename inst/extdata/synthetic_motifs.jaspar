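>AP1_A AP1_A_TGACTCA
A [   5   5  85   5   5   5  85 ]
C [   5   5   5  85   5  85   5 ]
G [   5  85   5   5   5   5   5 ]
T [  85   5   5   5  85   5   5 ]
>ATF_CREB ATF_CREB_TGACGTCA
A [   5   5  85   5   5   5   5  85 ]
C [   5   5   5  85   5   5  85   5 ]
G [   5  85   5   5  85   5   5   5 ]
T [  85   5   5   5   5  85   5   5 ]
>IRF_ISRE IRF_ISRE_AAAGTGAAAG
A [  85  85  85   5   5   5  85  85  85   5 ]
C [   5   5   5   5   5   5   5   5   5   5 ]
G [   5   5   5  85   5  85   5   5   5  85 ]
T [   5   5   5   5  85   5   5   5   5   5 ]
>NFKB_REL NFKB_REL_GGGACTTTCC
A [   5   5   5  85   5   5   5   5   5   5 ]
C [   5   5   5   5  85   5   5   5  85  85 ]
G [  85  85  85   5   5   5   5   5   5   5 ]
T [   5   5   5   5   5  85  85  85   5   5 ]
>ETS_PU1 ETS_PU1_AGAGGAAGTG
A [  85   5  85   5   5  85  85   5   5   5 ]
C [   5   5   5   5   5   5   5   5   5   5 ]
G [   5  85   5  85  85   5   5  85   5  85 ]
T [   5   5   5   5   5   5   5   5  85   5 ]
>CEBP CEBP_TTGCGCAA
A [   5   5   5   5   5   5  85  85 ]
C [   5   5   5  85   5  85   5   5 ]
G [   5   5  85   5  85   5   5   5 ]
T [  85  85   5   5   5   5   5   5 ]
>GATA GATA_AGATAAGA
A [  85   5  85   5  85  85   5  85 ]
C [   5   5   5   5   5   5   5   5 ]
G [   5  85   5   5   5   5  85   5 ]
T [   5   5   5  85   5   5   5   5 ]
>EBOX EBOX_CACGTGGC
A [   5  85   5   5   5   5   5   5 ]
C [  85   5  85   5   5   5   5  85 ]
G [   5   5   5  85   5  85  85   5 ]
T [   5   5   5   5  85   5   5   5 ]
>HOX HOX_GTAATTAG
A [   5   5  85  85   5   5  85   5 ]
C [   5   5   5   5   5   5   5   5 ]
G [  85   5   5   5   5   5   5  85 ]
T [   5  85   5   5  85  85   5   5 ]
>SOX SOX_AACAATGG
A [  85  85   5  85  85   5   5   5 ]
C [   5   5  85   5   5   5   5   5 ]
G [   5   5   5   5   5   5  85  85 ]
T [   5   5   5   5   5  85   5   5 ]
>RUNX RUNX_TGTGGTTT
A [   5   5   5   5   5   5   5   5 ]
C [   5   5   5   5   5   5   5   5 ]
G [   5  85   5  85  85   5   5   5 ]
T [  85   5  85   5   5  85  85  85 ]
>TEAD TEAD_GGAATGTG
A [   5   5  85  85   5   5   5   5 ]
C [   5   5   5   5   5   5   5   5 ]
G [  85  85   5   5   5  85   5  85 ]
T [   5   5   5   5  85   5  85   5 ]
>MEF2 MEF2_CTATTTAT
A [   5   5  85   5   5   5  85   5 ]
C [  85   5   5   5   5   5   5   5 ]
G [   5   5   5   5   5   5   5   5 ]
T [   5  85   5  85  85  85   5  85 ]
>ZNF ZNF_GCGGCGGC
A [   5   5   5   5   5   5   5   5 ]
C [   5  85   5   5  85   5   5  85 ]
G [  85   5  85  85   5  85  85   5 ]
T [   5   5   5   5   5   5   5   5 ]
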