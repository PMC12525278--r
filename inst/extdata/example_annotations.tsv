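geneSymbol	proteinChange	cdnaChange	inheritance	callerCount	mafNFE	mafAnyPopMax	caddPhred	acmgClass	consequence	mutationTaster	polyphen2	sift	fathmmMKL	spliceAI	gerp	constraintFlag	brainExpression	pathwayTags
FBXO7	p.(Ala248Thr)	c.742G>A	M	3	3.97e-06	3.97e-06	24.5	VUS	missense	1	1	1	1	0	1	0	1	LY/ATP
LRRK2	p.(Phe1436Leu)	c.4306T>C	M	3	NA	NA	24.1	VUS	missense	1	1	0	1	0	1	0	1	LY/VT/NR
GLA	p.Asp313Tyr	c.937G>T	M	3	0.00446	0.00446	18.3	B	missense	1	1	1	1	0	0	0	1	LY/ATP
ABL2	p.(Arg180Cys)	c.538C>T	unknown	3	8.79e-06	8.79e-06	34	LP	missense	1	1	1	1	0	0	0	1	NR
GLA	p.Asp313Tyr	c.937G>T	M	3	0.00446	0.00446	18.3	B	missense	1	1	1	1	0	0	0	1	LY/ATP
BORCS8	p.(Arg85His)	c.254G>A	unknown	3	1.35e-05	1.35e-05	22.8	VUS	missense	1	0	0	0	0	1	0	1	LY/MAPK
VPS33B	p.(Arg398Cys)	c.1192C>T	M	3	NA	NA	33	VUS	missense	1	1	1	1	0	1	0	1	LY/GLG/ATP
GLB1	p.Arg419Gln	c.1256G>A	F	3	7.06e-06	7.06e-06	35	LP	missense	1	0	0	1	1	1	0	1	LY/ATP/NR
DAPK1	p.(Arg666Gln)	c.1997G>A	M	3	6.22e-05	6.22e-05	25.4	VUS	missense	1	0	1	1	0	1	0	1	LY/ATP
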