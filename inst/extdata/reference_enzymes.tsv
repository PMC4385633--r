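ec_number	name	km	kcat
EC 1.8.1.9	glutathione reductase	0.404	0.39
EC 4.1.1.11	aspartate 1-decarboxylase	0.219	0.65
EC 1.1.1.1	alcohol dehydrogenase	0.41	1
EC 1.1.1.205	IMP dehydrogenase	1.7	1.9
EC 3.4.13.22	D-Ala-D-Ala dipeptidase	1	4.7
EC 4.1.1.1	pyruvate decarboxylase	1.8	1.2
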