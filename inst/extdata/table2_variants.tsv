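# Single-nucleotide variations identified in the evolved strains IMS0344
# and IMS0351 by whole-genome resequencing. Coding rows carry the
# ORF-internal nucleotide change (e.g. G1518C) and the reported amino-acid
# change; upstream rows carry the substitution and its distance 5' of the
# start codon. gene_alias records the published upstream gene spelling
# (SST4) alongside the allele name (stt4-2).
strain	allele	gene	gene_alias	location	nt_change	ref	alt	cds_pos	aa_ref	aa_pos	aa_alt	upstream_distance
IMS0344	rpn4-1	RPN4	NA	coding	G1518C	G	C	1518	K	506	N	NA
IMS0344	rtg1-1	RTG1	NA	coding	A235G	A	G	235	K	79	E	NA
IMS0344	ssk2-1	SSK2	NA	coding	C3974A	C	A	3974	P	1325	Q	NA
IMS0344	ubr1-1	UBR1	NA	coding	A3194G	A	G	3194	E	1065	G	NA
IMS0351	rpn4-2	RPN4	NA	coding	C1546T	C	T	1546	Q	516	*	NA
IMS0351	rtg1-2	RTG1	NA	coding	C256A	C	A	256	L	86	I	NA
IMS0351	nma111-2	NMA111	NA	coding	C545A	C	A	545	S	182	*	NA
IMS0351	ubr1-2	UBR1	NA	coding	C2129A	C	A	2129	S	710	*	NA
IMS0351	sto1-2	STO1	NA	coding	T2543G	T	G	2543	F	736	V	NA
IMS0351	rpl10-2	RPL10	NA	upstream	G>C	G	C	NA	NA	NA	NA	296
IMS0351	stt4-2	STT4	SST4	upstream	T>C	T	C	NA	NA	NA	NA	984
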