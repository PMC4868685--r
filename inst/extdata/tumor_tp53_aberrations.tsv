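# TP53 aberrations and MDM2 amplifications in the 25-tumor WGS cohort.
# One row per aberration event; samples with multiple events repeat their
# sample id and carry the wild-type allele frequency on the first row
# only. Frequencies are percent; copy_number only for amplifications.
#sample	gene	type	position	consequence	aberrant_af_pct	wt_af_pct	copy_number
PD7507a	TP53	Del (7.5 Mb)	Intron 9	TSS-exon i9 deleted	40	20
PD7507a	TP53	Trans	Intron 9	Loss of exon i9-3'UTR	40
PD7513a	TP53	Trans	Intron 1	Loss of exon2-3'UTR	40	25
PD7513a	TP53	Trans	Intron 1	Loss of TSS and exon1	35
PD7194a	TP53	Inv (50.3 Mb)	Intron 1	Loss of exon2-3'UTR	40	30
PD7194a	TP53	Trans	1.8 Mb upstream TP53 TSS	Gene loss (unbalanced translocation)	30
PD7197a	TP53	Small del (10 bp)	Exon5/intron5	Splice site disruption	55	45
PD13491a	TP53	Del (416 kb)	364 kb upstream - 31 kb downstream TP53 3'UTR	Gene loss	70	30
PD13492a	TP53	Trans	Intron 1	Loss of exon2-3'UTR	55	15
PD13492a	TP53	Trans	Intron 1	Loss of TSS and exon1	30
PD13493a	TP53	Del (72 kb)	50 kb upstream - 3 kb downstream TP53	Gene loss	60	40
PD13496a	TP53	Trans	76 kb downstream TP53	Gene loss	50	30
PD13496a	TP53	Trans	2 kb upstream TP53	Gene loss	20
PD7193	TP53	Del (93 kb)	Intron 1	Loss of exon2-3'UTR	40	30
PD7193	TP53	Trans	Intron 1	Loss of exon2-3'UTR	30
PD13485a	TP53	Del (9 kb)	Intron 9	Loss of exon i9-3'UTR	20	80
PD13486a	TP53	Trans	Intron 1	Loss of exon2-3'UTR	75	25
PD13484a	TP53	SNV	c.843C>A	p.D281E	32	68
PD13487a	TP53	SNV	c.713G>T	p.C238F	82	18
PD13488a	TP53	SNV	c.764T>C	p.I255T	62	38
PD7196a	TP53	SNV	c.818G>T	p.R273L	47	53
PD13490a	TP53	SNV	c.824G>A	p.C275Y	72	28
PD7508a	MDM2	High level Ampl	chr12 q15	Total CN of 20			20
PD7510a	MDM2	High level Ampl	chr12 q15	Total CN of 60			60
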