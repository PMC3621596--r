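# Strains of the study: references, marker deletants, the two evolved
# lineages and their backcross generations. mutated_alleles is the
# semicolon-separated list of evolved alleles carried by haploid strains
# (NA for reference/diploid/collection entries); generation marks the
# backcross series position.
strain	mating_type	ploidy	generation	lineage	mutated_alleles	description
BY4741	a	haploid	reference	NA	NA	MATa his3-d1 leu2-d met15-d ura3-d
KO_collection	a	haploid	reference	NA	NA	MATa his3-d1 leu2-d met15-d ura3-d ORFd::KanMX
CEN.PK113-7D	a	haploid	reference	NA	NA	MATa
CEN.PK113-1A	alpha	haploid	reference	NA	NA	MATalpha
IMK439	alpha	haploid	marker_deletant	NA	NA	MATalpha ura3d::KanMX
IMK440	a	haploid	marker_deletant	NA	NA	MATa ura3d::KanMX
IMS0344	a	haploid	evolved	1	rpn4-1;rtg1-1;ubr1-1;ssk2-1	MATa rpn4-1 rtg1-1 ubr1-1 ssk2-1
IMS0345	a/alpha	diploid	cross1	1	rpn4-1;rtg1-1;ubr1-1;ssk2-1	heterozygous diploid, URA3/ura3d::KanMX
IMS0346	alpha	haploid	F1	1	rpn4-1;rtg1-1;ubr1-1;ssk2-1	MATalpha rpn4-1 rtg1-1 ubr1-1 ssk2-1
IMS0347	a/alpha	diploid	cross2	1	rpn4-1;rtg1-1;ubr1-1;ssk2-1	heterozygous diploid, URA3/ura3d::KanMX
IMS0348	alpha	haploid	F2	1	rpn4-1;rtg1-1;ubr1-1;ssk2-1	MATalpha rpn4-1 rtg1-1 ubr1-1 ssk2-1
IMS0349	a/alpha	diploid	cross3	1	rpn4-1;rtg1-1;ubr1-1;ssk2-1	heterozygous diploid, URA3/ura3d::KanMX
IMS0350	a	haploid	F3	1	rpn4-1;rtg1-1;ssk2-1	MATa rpn4-1 rtg1-1 ssk2-1
IMS0351	a	haploid	evolved	2	rpn4-2;rtg1-2;ubr1-2;nma111-2;rpl10-2;sto1-2;stt4-2	MATa rpn4-2 rtg1-2 ubr1-2 nma111-2 rpl10-2 sto1-2 sst4-2
IMS0352	a/alpha	diploid	cross1	2	rpn4-2;rtg1-2;ubr1-2;nma111-2;rpl10-2;sto1-2;stt4-2	heterozygous diploid, URA3/ura3d::KanMX
IMS0353	a	haploid	F1	2	rpn4-2;rtg1-2;nma111-2;rpl10-2	MATa rpn4-2 rtg1-2 nma111-2 rpl10-2
IMS0354	a/alpha	diploid	cross2	2	rpn4-2;rtg1-2;nma111-2;rpl10-2	heterozygous diploid, URA3/ura3d::KanMX
IMS0355	a	haploid	F2	2	rpn4-2;rtg1-2;nma111-2;rpl10-2	MATa rpn4-2 rtg1-2 nma111-2 rpl10-2
IMS0356	a/alpha	diploid	cross3	2	rpn4-2;rtg1-2;nma111-2;rpl10-2	heterozygous diploid, URA3/ura3d::KanMX
IMS0357	a	haploid	F3	2	rpn4-2;rtg1-2;nma111-2	MATa rpn4-2 rtg1-2 nma111-2
IMI218	a	haploid	reverse_engineered	NA	rpn4-1	MATa RPN4pr::KanMX RPN4pr-rpn4-1
IMI238	a	haploid	reverse_engineered	NA	rtg1-1	MATa RTG1pr::KanMX RTG1pr-rtg1-1
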