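>341F amplification_forward 16S V3-V4
ACACTCTTTCCCTACACGACGCTCTTCCGATCTCCTACGGGRSGCAGCAG
>785R amplification_reverse 16S V3-V4
ACACTCTTTCCCTACACGACGCTCTTCCGATCTGACTACHVGGGTATCTAATCC
>1389F amplification_forward 18S V9
ACACTCTTTCCCTACACGACGCTCTTCCGATCTTTGTACACACCGCCC
>1015R amplification_reverse 18S V9
ACACTCTTTCCCTACACGACGCTCTTCCGATCTCCTTCYGCAGGTTCACCTAC
>BP-F_Hi_V9 blocking [SpcC3]
ATTTAGTGAGGTCTCCGGACGTG
>BP-R_Hi_V9 blocking [SpcC3]
GGTCAACTTTTGCGAAACAACC
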