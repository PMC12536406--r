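resname	variant	elety	charge	epsilon	sigma	rborn
*	std	N	-0.47	0.200	3.296	1.55
*	std	H	0.31	0.046	0.400	1.20
*	std	HN	0.31	0.046	0.400	1.20
*	std	CA	0.07	0.032	4.054	1.70
*	std	HA	0.09	0.022	2.352	1.30
*	std	C	0.51	0.110	3.564	1.70
*	std	O	-0.51	0.120	3.029	1.50
*	std	OXT	-0.67	0.120	3.029	1.50
*	std	CB	0.00	0.080	4.500	2.00
GLY	std	CA	-0.02	0.032	4.054	1.70
GLY	std	HA1	0.09	0.022	2.352	1.30
GLY	std	HA2	0.09	0.022	2.352	1.30
ASP	std	CB	-1.00	0.080	4.500	2.00
GLU	std	CB	-1.00	0.080	4.500	2.00
LYS	std	CB	1.00	0.080	4.500	2.00
ARG	std	CB	1.00	0.080	4.500	2.00
PRO	std	N	-0.29	0.200	3.296	1.55
PRO	std	CA	0.02	0.032	4.054	1.70
PRO	std	CB	0.18	0.080	4.500	2.00
CYS	std	CB	0.07	0.080	4.500	2.00
CYS	std	SG	-0.23	0.450	3.564	1.80
CYS	std	HG1	0.16	0.046	0.400	1.20
CYS	disulfide	CB	0.08	0.080	4.500	2.00
CYS	disulfide	SG	-0.08	0.450	3.564	1.80
*	amide	NT	-0.62	0.200	3.296	1.55
*	amide	HT1	0.31	0.046	0.400	1.20
*	amide	HT2	0.31	0.046	0.400	1.20
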