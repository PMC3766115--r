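motif_id	name	motif_class	effector	score_threshold	distribution_group	reported_sites	experimental
RF00059	TPP (THI element)	riboswitch	thiamin pyrophosphate	30	A	564	known
RF00174	Cobalamin (B12 element)	riboswitch	adenosylcobalamin	30	A	536	known
RF00504	Glycine	riboswitch	glycine	30	A	324	known
RF00080	yybP-ykoY	riboswitch	unknown	30	A	232	predicted
RF00050	FMN (RFN element)	riboswitch	flavin mononucleotide	30	A	233	known
RF00162	SAM (S-box)	riboswitch	S-adenosylmethionine	30	B	257	known
RF00515	pyrR	pyrR	-	30	B	211	known
RF00168	Lysine (L-box)	riboswitch	lysine	30	B	186	known
RF00167	Purine (G-box)	riboswitch	guanine, adenine	30	B	141	known
RF01051	GEMM	riboswitch	cyclic di-GMP	30	B	89	known
RF00522	PreQ1	riboswitch	pre-queuosine_1	30	B	72	known
RF01055	MOCO	riboswitch	molybdenum or tungsten cofactor	30	B	62	known
RF00379	ydaO-yuaA	riboswitch	ATP	30	B	59	known
RF00442	ykkC-yxkD	riboswitch	unknown	30	B	58	predicted
RF01068	mini-ykkC	riboswitch	unknown	30	B	67	predicted
RF00380	ykoK (M-box)	riboswitch	magnesium	30	B	48	known
RF00234	glmS	riboswitch	glucosamine-6-phosphate	30	B	44	known
RF01057	SAH	riboswitch	S-adenosylhomocysteine	30	B	27	known
RF00521	SAM-Alpha	riboswitch	S-adenosylmethionine	30	C	39	known
RF00517	serC	riboswitch	unknown	30	C	32	predicted
RF01831	THF	riboswitch	tetrahydrofolate	30	C	23	known
RF01054	PreQ1-II	riboswitch	pre-queuosine_1	30	C	17	known
RF01070	sucA	riboswitch	unknown	30	C	14	predicted
RF01739	glnA	riboswitch	glutamine	30	C	13	known
RF00634	SAM-IV	riboswitch	S-adenosylmethionine	30	C	13	known
RF01727	SAM-SAH	riboswitch	S-adenosylmethionine, S-adenosylhomocysteine	30	C	13	known
RF01767	Smk-box	riboswitch	S-adenosylmethionine	30	C	13	known
RF00518	speF	riboswitch	unknown	30	C	12	predicted
RF01724	SAM-Chlorobi	riboswitch	S-adenosylmethionine	30	C	11	predicted
RF00516	ylbH	riboswitch	unknown	30	C	10	predicted
RF00520	ybhL	riboswitch	unknown	30	C	8	predicted
RF01056	Mg sensor	riboswitch	magnesium	30	C	5	known
RF00557	L10 leader	ribosomal_leader	-	30	D	108	predicted
RF00114	S15 leader	ribosomal_leader	-	30	D	98	known
RF00558	L20 leader	ribosomal_leader	-	30	D	75	predicted
RF00559	L21 leader	ribosomal_leader	-	30	D	67	predicted
RF00556	L19 leader	ribosomal_leader	-	30	D	61	predicted
RF00555	L13 leader	ribosomal_leader	-	30	D	43	predicted
RF00514	His leader	aa_leader	-	30	E	49	known
RF00513	Trp leader	aa_leader	-	30	E	48	known
RF00506	Thr leader	aa_leader	-	30	E	45	known
RF00512	Leu leader	aa_leader	-	30	E	43	known
RF00230	T-box	tbox	-	30	F	1134	known
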