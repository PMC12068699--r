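sampleId	geneId	aCount	totalCount
S0001	gene1	41	72
S0002	gene1	36	57
S0003	gene1	31	65
S0004	gene1	11	46
S0005	gene1	20	42
S0006	gene1	37	64
S0007	gene1	8	81
S0008	gene1	29	57
S0009	gene1	35	65
S0010	gene1	10	59
S0011	gene1	40	84
S0012	gene1	22	45
S0013	gene1	20	47
S0014	gene1	35	69
S0015	gene1	39	71
S0016	gene1	31	63
S0017	gene1	21	38
S0018	gene1	18	40
S0019	gene1	21	54
S0020	gene1	44	56
S0021	gene1	28	60
S0022	gene1	25	53
S0023	gene1	30	67
S0024	gene1	30	69
S0025	gene1	26	41
S0026	gene1	19	47
S0027	gene1	12	43
S0028	gene1	29	64
S0029	gene1	34	59
S0030	gene1	25	65
S0031	gene1	35	51
S0032	gene1	45	69
S0033	gene1	37	82
S0034	gene1	25	56
S0035	gene1	31	58
S0036	gene1	54	80
S0037	gene1	41	69
S0038	gene1	25	55
S0039	gene1	30	53
S0040	gene1	13	40
S0041	gene1	45	81
S0042	gene1	33	80
S0043	gene1	41	72
S0044	gene1	28	56
S0045	gene1	29	59
S0046	gene1	46	71
S0047	gene1	16	41
S0048	gene1	12	44
S0049	gene1	37	81
S0050	gene1	37	44
S0051	gene1	30	71
S0052	gene1	21	43
S0053	gene1	33	58
S0054	gene1	30	55
S0055	gene1	35	58
S0056	gene1	29	65
S0057	gene1	49	78
S0058	gene1	30	58
S0059	gene1	20	43
S0060	gene1	10	58
S0061	gene1	20	60
S0062	gene1	17	37
S0063	gene1	8	65
S0064	gene1	10	50
S0065	gene1	24	52
S0066	gene1	40	64
S0067	gene1	26	57
S0068	gene1	30	60
S0069	gene1	13	38
S0070	gene1	14	38
S0071	gene1	25	44
S0072	gene1	32	72
S0073	gene1	19	32
S0074	gene1	27	56
S0075	gene1	31	56
S0076	gene1	44	48
S0077	gene1	32	63
S0078	gene1	28	47
S0079	gene1	27	39
S0080	gene1	26	56
S0081	gene1	30	53
S0082	gene1	40	82
S0083	gene1	18	34
S0084	gene1	32	52
S0085	gene1	42	56
S0086	gene1	43	71
S0087	gene1	27	45
S0088	gene1	19	51
S0089	gene1	32	67
S0090	gene1	31	54
S0091	gene1	20	40
S0092	gene1	33	52
S0093	gene1	26	52
S0094	gene1	16	40
S0095	gene1	25	56
S0096	gene1	25	59
S0097	gene1	33	77
S0098	gene1	28	65
S0099	gene1	15	47
S0100	gene1	16	58
S0101	gene1	16	55
S0102	gene1	13	34
S0103	gene1	31	60
S0104	gene1	54	91
S0105	gene1	25	46
S0106	gene1	26	60
S0107	gene1	61	80
S0108	gene1	30	63
S0109	gene1	21	61
S0110	gene1	24	72
S0111	gene1	12	62
S0112	gene1	31	45
S0113	gene1	9	56
S0114	gene1	53	96
S0115	gene1	14	60
S0116	gene1	35	82
S0117	gene1	21	61
S0118	gene1	26	52
S0119	gene1	26	62
S0120	gene1	48	84
S0121	gene1	29	63
S0122	gene1	28	49
S0123	gene1	43	78
S0124	gene1	34	70
S0125	gene1	36	46
S0126	gene1	19	52
S0127	gene1	30	59
S0128	gene1	17	39
S0129	gene1	16	42
S0130	gene1	63	81
S0131	gene1	37	51
S0132	gene1	14	37
S0133	gene1	4	37
S0134	gene1	14	34
S0135	gene1	17	43
S0136	gene1	19	33
S0137	gene1	46	71
S0138	gene1	16	38
S0139	gene1	43	59
S0140	gene1	7	37
S0141	gene1	23	38
S0142	gene1	33	64
S0143	gene1	36	66
S0144	gene1	43	61
S0145	gene1	47	66
S0146	gene1	16	52
S0147	gene1	33	71
S0148	gene1	29	57
S0149	gene1	43	83
S0150	gene1	29	52
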