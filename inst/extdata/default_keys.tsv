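key_id	smarts	description	unit
0	[N+](=O)[O-]	nitro group	1
1	c[N+](=O)[O-]	aromatic nitro	0
2	[N+0]c1ccccc1	aromatic amine (N on six-membered aromatic ring)	0
3	C[N+0]c1ccccc1	secondary aromatic amine (one carbon substituent)	0
4	C[N+0](C)c1ccccc1	tertiary aromatic amine (two carbon substituents)	0
5	[N+0]c1ccccc1C(=O)O	aromatic amine with ortho carboxylic acid	0
6	C1CO1	epoxide	0
7	C1CN1	aziridine	0
8	N=N	azo	1
9	cN=Nc	aromatic azo	0
10	[N+0]=O	nitroso	1
11	N[N+0]=O	N-nitroso	1
12	C(=O)O	carboxylic acid / ester carbonyl-oxygen	1
13	C(=O)Cl	acyl chloride	1
14	C=O	carbonyl	1
15	C#N	nitrile	1
16	S(=O)=O	sulfonyl	1
17	CCl	aliphatic chloride	0
18	CBr	aliphatic bromide	0
19	CI	aliphatic iodide	0
20	CF	aliphatic fluoride	0
21	cCl	aromatic chloride	0
22	cBr	aromatic bromide	0
23	c1ccccc1	benzene ring	0
24	c1ccc2ccccc2c1	naphthalene system	0
25	c1ccoc1	furan ring	0
26	c1ccsc1	thiophene ring	0
27	c1ccncc1	pyridine ring	0
28	c1ccnc1	five-membered aromatic N ring	0
29	Oc1ccccc1	phenol / aryl ether oxygen	0
30	COc1ccccc1	aryl methoxy-type ether	0
31	CN	aliphatic amine	0
32	CO	aliphatic oxygen on carbon	0
33	C1CCCCC1	cyclohexane ring	0
34	C1CCCC1	cyclopentane ring	0
35	cC	carbon substituent on aromatic ring	0
36	c1ccccc1-c1ccccc1	biphenyl linkage	0
37	c1ccc2c(c1)ccc1ccccc21	phenanthrene system (bay-region PAH proxy)	0
38	C=Cc1ccccc1	vinyl aromatic	0
39	C=C	alkene	0
40	C#C	alkyne	0
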