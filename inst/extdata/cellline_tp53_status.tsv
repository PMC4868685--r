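# p53-pathway status of the 11 sequenced osteosarcoma cell lines.
# mechanism: rearrangement (genomic rearrangement of TP53), mutation
# (point mutation), indel (small intragenic deletion), mdm2_amplification.
# tp53_intron: intron carrying the rearrangement breakpoint, if any.
# p53_functional: truth for the radiation-damage assay (all deficient).
#cell_line	mechanism	tp53_intron	detail	p53_functional
KPD	rearrangement	1	fusion keeps only non-coding exon 1 (DDX39B partner)	deficient
MG-63	rearrangement	1	translocation; TP53-VAV1 and read-through TP53-EMR1 transcripts	deficient
Saos-2	rearrangement	1	long deletion after exon 1; TP53-SAT2 transcript	deficient
ZK-58	rearrangement	1	translocation t(5;17); transcript keeps exon 1 only	deficient
IOR/OS15	rearrangement	8	TP53-PPRAD fusion retains exons 1-8 (aa 1-306)	deficient
IOR/OS18	rearrangement	4	translocation t(14;17); transcript keeps exons 5-11 (aa 126-393)	deficient
IOR/OS10	rearrangement	9	truncated transcript ends after exon 9 (aa 331)	deficient
IOR/SARG	mutation	NA	homozygous stop at aa 205	deficient
IOR/MOS	indel	NA	small deletion affecting TAD2 and DNA-binding domain	deficient
MHM	mdm2_amplification	NA	wild-type TP53; MDM2 amplified 10-fold	deficient
OSA	mdm2_amplification	NA	wild-type TP53; MDM2 amplified	deficient
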