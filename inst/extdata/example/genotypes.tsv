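variantId	sampleId	cls
var1	S0001	HOM
var1	S0002	HOM
var1	S0003	HOM
var1	S0004	HET
var1	S0005	HET
var1	S0006	HET
var1	S0007	HET
var1	S0008	HOM
var1	S0009	HET
var1	S0010	HET
var1	S0011	HOM
var1	S0012	HET
var1	S0013	HOM
var1	S0014	HOM
var1	S0015	HOM
var1	S0016	HOM
var1	S0017	HOM
var1	S0018	HOM
var1	S0019	HOM
var1	S0020	HET
var1	S0021	HET
var1	S0022	HOM
var1	S0023	HOM
var1	S0024	HOM
var1	S0025	HOM
var1	S0026	HET
var1	S0027	HOM
var1	S0028	HET
var1	S0029	HOM
var1	S0030	HET
var1	S0031	HET
var1	S0032	HET
var1	S0033	HOM
var1	S0034	HET
var1	S0035	HOM
var1	S0036	HET
var1	S0037	HOM
var1	S0038	HOM
var1	S0039	HET
var1	S0040	HET
var1	S0041	HOM
var1	S0042	HOM
var1	S0043	HOM
var1	S0044	HOM
var1	S0045	HOM
var1	S0046	HOM
var1	S0047	HET
var1	S0048	HET
var1	S0049	HOM
var1	S0050	HET
var1	S0051	HOM
var1	S0052	HOM
var1	S0053	HOM
var1	S0054	HET
var1	S0055	HOM
var1	S0056	HET
var1	S0057	HET
var1	S0058	HOM
var1	S0059	HOM
var1	S0060	HET
var1	S0061	HET
var1	S0062	HOM
var1	S0063	HET
var1	S0064	HET
var1	S0065	HET
var1	S0066	HOM
var1	S0067	HOM
var1	S0068	HET
var1	S0069	HET
var1	S0070	HOM
var1	S0071	HOM
var1	S0072	HOM
var1	S0073	HOM
var1	S0074	HOM
var1	S0075	HOM
var1	S0076	HET
var1	S0077	HOM
var1	S0078	HOM
var1	S0079	HET
var1	S0080	HOM
var1	S0081	HET
var1	S0082	HOM
var1	S0083	HOM
var1	S0084	HET
var1	S0085	HET
var1	S0086	HET
var1	S0087	HOM
var1	S0088	HOM
var1	S0089	HOM
var1	S0090	HOM
var1	S0091	HET
var1	S0092	HOM
var1	S0093	HOM
var1	S0094	HOM
var1	S0095	HOM
var1	S0096	HET
var1	S0097	HOM
var1	S0098	HET
var1	S0099	HET
var1	S0100	HET
var1	S0101	HET
var1	S0102	HOM
var1	S0103	HOM
var1	S0104	HOM
var1	S0105	HOM
var1	S0106	HOM
var1	S0107	HET
var1	S0108	HET
var1	S0109	HET
var1	S0110	HOM
var1	S0111	HET
var1	S0112	HET
var1	S0113	HET
var1	S0114	HOM
var1	S0115	HET
var1	S0116	HET
var1	S0117	HOM
var1	S0118	HOM
var1	S0119	HET
var1	S0120	HET
var1	S0121	HOM
var1	S0122	HOM
var1	S0123	HET
var1	S0124	HET
var1	S0125	HET
var1	S0126	HOM
var1	S0127	HOM
var1	S0128	HOM
var1	S0129	HOM
var1	S0130	HET
var1	S0131	HET
var1	S0132	HET
var1	S0133	HET
var1	S0134	HOM
var1	S0135	HET
var1	S0136	HET
var1	S0137	HET
var1	S0138	HOM
var1	S0139	HET
var1	S0140	HET
var1	S0141	HOM
var1	S0142	HOM
var1	S0143	HOM
var1	S0144	HET
var1	S0145	HET
var1	S0146	HET
var1	S0147	HOM
var1	S0148	HOM
var1	S0149	HOM
var1	S0150	HOM
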