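patient	arm	histology	bestChangePct	worstChangePct	newLesions	clinicalProgression	pfsMonths	pfsEvent	cbExcluded	monocyteCluster
PT01	aPD-L1	EAC	-100	-100	FALSE	FALSE	15.2	0	FALSE	high
PT02	aPD-L1	EAC	-52	-40	FALSE	FALSE	14	0	FALSE	high
PT03	aPD-L1	EAC	-52	-40	FALSE	FALSE	14	0	FALSE	high
PT04	aPD-L1	EAC	-52	-40	FALSE	FALSE	14	0	FALSE	high
PT05	aPD-L1	EAC	-52	-40	FALSE	FALSE	14	0	FALSE	high
PT06	aPD-L1	EAC	8	12	FALSE	FALSE	6.1	1	FALSE	high
PT07	aPD-L1	EAC	8	12	FALSE	FALSE	6.1	1	FALSE	high
PT08	aPD-L1	EAC	8	12	FALSE	FALSE	6.1	1	FALSE	high
PT09	aPD-L1	EAC	25	31	FALSE	FALSE	3.4	1	FALSE	other
PT10	aPD-L1	EAC	25	31	FALSE	FALSE	3.4	1	FALSE	other
PT11	aPD-L1	EAC	5	5	FALSE	FALSE	7.7	1	FALSE	high
PT12	aPD-L1	ESCC	30	34	FALSE	FALSE	2.8	1	FALSE	NA
PT13	aPD-L1+37.5	EAC	-35	-10	FALSE	FALSE	9.8	1	FALSE	other
PT14	aPD-L1+37.5	EAC	-35	-10	FALSE	FALSE	9.8	1	FALSE	other
PT15	aPD-L1+37.5	EAC	28	36	FALSE	FALSE	4.2	1	FALSE	other
PT16	aPD-L1+37.5	EAC	28	36	FALSE	FALSE	4.2	1	FALSE	other
PT17	aPD-L1+37.5	EAC	28	36	FALSE	FALSE	4.2	1	FALSE	other
PT18	aPD-L1+75	EAC	-45	-30	FALSE	FALSE	16.5	0	FALSE	high
PT19	aPD-L1+75	EAC	-45	-30	FALSE	FALSE	16.5	0	FALSE	high
PT20	aPD-L1+75	EAC	-45	-30	FALSE	FALSE	16.5	0	FALSE	high
PT21	aPD-L1+75	EAC	-60	-55	FALSE	FALSE	13.1	0	FALSE	other
PT22	aPD-L1+75	EAC	-60	-55	FALSE	FALSE	13.1	0	FALSE	other
PT23	aPD-L1+75	EAC	-60	-55	FALSE	FALSE	13.1	0	FALSE	other
PT24	aPD-L1+75	EAC	-60	-55	FALSE	FALSE	13.1	0	FALSE	other
PT25	aPD-L1+75	EAC	-38	-20	FALSE	FALSE	12	1	FALSE	other
PT26	aPD-L1+75	EAC	-33	-33	FALSE	FALSE	18	0	FALSE	NA
PT27	aPD-L1+75	GEJ	-41	-35	FALSE	FALSE	14.4	0	FALSE	NA
PT28	aPD-L1+75	EAC	6	15	FALSE	FALSE	8.3	1	FALSE	other
PT29	aPD-L1+75	EAC	6	15	FALSE	FALSE	8.3	1	FALSE	other
PT30	aPD-L1+75	EAC	6	15	FALSE	FALSE	8.3	1	FALSE	other
PT31	aPD-L1+75	EAC	6	15	FALSE	FALSE	8.3	1	FALSE	other
PT32	aPD-L1+75	EAC	22	26	FALSE	FALSE	5.5	1	FALSE	other
PT33	aPD-L1+75	EAC	22	26	FALSE	FALSE	5.5	1	FALSE	other
PT34	aPD-L1+75	EAC	22	26	FALSE	FALSE	5.5	1	FALSE	other
PT35	aPD-L1+75	EAC	22	26	FALSE	FALSE	5.5	1	FALSE	other
PT36	aPD-L1+75	EAC	10	18	FALSE	FALSE	9.9	1	FALSE	NA
PT37	aPD-L1+75	GEJ	35	42	FALSE	FALSE	2.1	1	FALSE	NA
PT38	aPD-L1+75	EAC	-5	2	FALSE	FALSE	20	0	TRUE	NA
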