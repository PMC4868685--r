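# SYNTHETIC p53 domain coordinate table (editable). Boundaries are chosen
# to be consistent with the domain semantics used in the cohort analyses
# (TAD = transactivation domain, DBD = DNA-binding domain, NLS = nuclear
# localization signal, OD = oligomerization domain, BR = basic region):
# truncation after aa 306 removes most of the NLS and everything C-terminal;
# retention of aa 126-393 removes both TADs and the first 25 aa of the DBD;
# a stop at aa 205 removes the last 87 aa of the DBD; truncation after
# aa 331 removes the complete OD and BR. Not a curated UniProt annotation.
#protein_length	393
#domain	start_aa	end_aa
TAD1	1	42
TAD2	43	63
DBD	101	291
NLS	305	322
OD	332	355
BR	363	393
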