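# Packaged oligo table (v1). Published amplification primers for the 16S
# V3-V4 and 18S V9 marker regions, and the two Hermetia illucens (black
# soldier fly) V9 elongation-arrest blocking primers. All amplification
# primers share one Illumina adapter tail; blocking primers carry a 3' C3
# spacer and no tail.
name	role	adapter_tail	gene_specific	terminator
341F	amplification_forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	CCTACGGGRSGCAGCAG	none
785R	amplification_reverse	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	GACTACHVGGGTATCTAATCC	none
1389F	amplification_forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	TTGTACACACCGCCC	none
1015R	amplification_reverse	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	CCTTCYGCAGGTTCACCTAC	none
BP-F_Hi_V9	blocking		ATTTAGTGAGGTCTCCGGACGTG	C3_spacer
BP-R_Hi_V9	blocking		GGTCAACTTTTGCGAAACAACC	C3_spacer
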