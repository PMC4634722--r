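# FnrL-bound recognition sequences in Rhodobacter capsulatus SB1003:
# ChIP-supported directly regulated genes with a consensus binding site.
# location: a = site within the coding region, b = site in the upstream
# intergenic / promoter region. regulation: + activated / - repressed by
# FnrL; fold_change from wild type vs deletion-mutant RNA-seq.
locus_id	gene_name	recognition_sequence	location	enrichment	regulation	fold_change	cog
RCC01157	ccoN	TTGATCAAGGTCAA	b	25	+	1.55	C
RCC01157	ccoN	ATGATGTCGATCAA	a	25	+	1.55	C
RCC00728	nnrU	CTGCCGCAGATCAA	a	4	+	1.47	C
RCC00732	sdhD	ATGATGAGCGTCAA	b	3	+	1.41	C
RCC00022	oxidoreductase	ATGATTTACCGCAA	a	5	+	1.38	C
RCC01724	speB1	TTGATCTGCGTCAA	b	10	+	1.33	E
RCC00400	pyrB	CTGACGCAGATCAA	a	10	+	1.47	F
RCC00731	sdhC	ATGATGAGCGTCAA	a	3	+	1.53	G
RCC00480	rpsU	CTGATGCAACTCAA	b	4	+	1.57	I
RCC01495	fusA	TTGGCATGGGTCAA	b	17	+	3.48	J
RCC03240	exodeoxyribonuclease_V	ATGCGCCAGATCAA	a	4	-	-1.34	L
RCC02193	DNA-3-methyladenine_glycosylase_II	ATGACGCGGATCAA	a	4	-	-1.97	L
RCC02479	lipoprotein	CTGATGCAGCGCAA	b	13	+	1.42	M
RCC00481	mcpI	CTGACCGAGATCAA	a	4	-	-1.53	N
RCC03524	flaF	CTGATCGACATCAA	a	4	-	-1.87	N
RCC03523	flbT	CTGATCGACATCAA	b	4	-	-2.14	N
RCC01156	uspA	TTGACGCGGATCAA	b	26	+	5.21	O
RCC01723	ccpA	TTGATCTGCGTCAA	b	10	+	3.81	O
RCC02829	putative_hemolysin	TTGACCCTCGTCAA	a	6	-	-1.64	O
RCC02684	polyphosphate_kinase_2	TTGATGCGTGTCAA	b	14	+	2.25	R
RCC02665	hemolysin-type_calcium-binding	ATGACCGGCGTCAA	a	9	+	1.46	R
RCC00435	hypothetical_protein	CTGACCCAGATCAA	b	21	+	9.19	S
RCC00901	hypothetical_protein	TTGACACGGGTCAA	b	10	+	6.87	S
RCC00747	hypothetical_protein	ATGACGCAGATCAA	b	5	+	3.78	S
RCC00424	hypothetical_protein	ATGATTCAGATCAA	b	20	+	3.51	S
RCC02321	hypothetical_protein	ATGATCCGGATCAA	b	26	+	2.17	S
RCC02988	hypothetical_protein	TTGACCCAGATCAA	b	8	-	-1.41	S
RCC01027	hypothetical_protein	TTGACCAAGGTCAA	b	6	-	-1.64	S
RCC02849	dorS	TTGATCGGGATCAA	a	26	+	4.53	T
RCC02590	dksA	TTGATTCAGGTCAA	b	28	+	1.79	T
RCC00667	aerR	ATGCTCGAGTTCAA	b	8	+	1.39	X
RCC00666	bchF	ATGACATGGGTCAA	b	8	+	1.39	X
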