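# Fusion transcripts with a confirmed underlying genomic rearrangement in
# the three concordant cell lines (19 of 182 fusion transcripts across the
# four fully sequenced lines; the fourth line, IOR/OS18, had none of 160).
# read_through: the rearrangement breakend lies in the gene next to the
# reported 3' partner (one translocation explaining two transcripts).
#sample	gene_fusion	rearrangement_type	read_through
IOR/OS15	PMP22-ELOVL5	Translocation	no
IOR/OS15	GCC2-CCDC73	Translocation	no
IOR/OS15	RAI1-CLIC5	Translocation	no
IOR/OS15	TP53-PPRAD	Translocation	no
IOR/OS15	MRPL39-MAML3	Translocation and deletion	no
IOR/OS15	PLXNA2-RUNX1	Translocation	no
IOR/OS15	SCO1-CLIC5	Translocation	no
IOR/OS15	EIF2S1-RBM25	Deletion	no
IOR/OS15	BAZ1A-NUMB	Deletion	no
IOR/OS15	CDC5L-BTBD9	Inversion	no
IOR/OS15	MRPL39-NRIP1	Inversion	no
MG-63	DNER-ELL2	Translocation	no
MG-63	CLIP4-EPHB4	Translocation	no
MG-63	TP53-VAV1	Translocation	no
MG-63	TP53-EMR1	Translocation	yes
MG-63	MROH1-PARP10	Inversion	no
MG-63	BNC2-MTAP	Inversion	no
ZK-58	CREBBP-TFAP4	Deletion	no
ZK-58	GDPD5-MAP6	Deletion	no
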