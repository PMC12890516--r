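protein_id	is_effect	direction	is_restored
prot_0001	FALSE	NA	FALSE
prot_0002	FALSE	NA	FALSE
prot_0003	FALSE	NA	FALSE
prot_0004	FALSE	NA	FALSE
prot_0005	FALSE	NA	FALSE
prot_0006	FALSE	NA	FALSE
prot_0007	FALSE	NA	FALSE
prot_0008	FALSE	NA	FALSE
prot_0009	FALSE	NA	FALSE
prot_0010	FALSE	NA	FALSE
prot_0011	FALSE	NA	FALSE
prot_0012	FALSE	NA	FALSE
prot_0013	FALSE	NA	FALSE
prot_0014	FALSE	NA	FALSE
prot_0015	FALSE	NA	FALSE
prot_0016	FALSE	NA	FALSE
prot_0017	FALSE	NA	FALSE
prot_0018	TRUE	down	TRUE
prot_0019	FALSE	NA	FALSE
prot_0020	FALSE	NA	FALSE
prot_0021	FALSE	NA	FALSE
prot_0022	FALSE	NA	FALSE
prot_0023	FALSE	NA	FALSE
prot_0024	FALSE	NA	FALSE
prot_0025	FALSE	NA	FALSE
prot_0026	FALSE	NA	FALSE
prot_0027	FALSE	NA	FALSE
prot_0028	FALSE	NA	FALSE
prot_0029	FALSE	NA	FALSE
prot_0030	FALSE	NA	FALSE
prot_0031	TRUE	down	FALSE
prot_0032	TRUE	down	TRUE
prot_0033	FALSE	NA	FALSE
prot_0034	FALSE	NA	FALSE
prot_0035	TRUE	up	TRUE
prot_0036	FALSE	NA	FALSE
prot_0037	FALSE	NA	FALSE
prot_0038	FALSE	NA	FALSE
prot_0039	FALSE	NA	FALSE
prot_0040	FALSE	NA	FALSE
prot_0041	FALSE	NA	FALSE
prot_0042	FALSE	NA	FALSE
prot_0043	FALSE	NA	FALSE
prot_0044	FALSE	NA	FALSE
prot_0045	FALSE	NA	FALSE
prot_0046	FALSE	NA	FALSE
prot_0047	FALSE	NA	FALSE
prot_0048	FALSE	NA	FALSE
prot_0049	FALSE	NA	FALSE
prot_0050	FALSE	NA	FALSE
prot_0051	FALSE	NA	FALSE
prot_0052	FALSE	NA	FALSE
prot_0053	FALSE	NA	FALSE
prot_0054	FALSE	NA	FALSE
prot_0055	FALSE	NA	FALSE
prot_0056	FALSE	NA	FALSE
prot_0057	FALSE	NA	FALSE
prot_0058	FALSE	NA	FALSE
prot_0059	FALSE	NA	FALSE
prot_0060	FALSE	NA	FALSE
prot_0061	FALSE	NA	FALSE
prot_0062	TRUE	up	TRUE
prot_0063	FALSE	NA	FALSE
prot_0064	FALSE	NA	FALSE
prot_0065	FALSE	NA	FALSE
prot_0066	FALSE	NA	FALSE
prot_0067	FALSE	NA	FALSE
prot_0068	TRUE	down	TRUE
prot_0069	FALSE	NA	FALSE
prot_0070	FALSE	NA	FALSE
prot_0071	FALSE	NA	FALSE
prot_0072	FALSE	NA	FALSE
prot_0073	FALSE	NA	FALSE
prot_0074	FALSE	NA	FALSE
prot_0075	FALSE	NA	FALSE
prot_0076	FALSE	NA	FALSE
prot_0077	FALSE	NA	FALSE
prot_0078	FALSE	NA	FALSE
prot_0079	FALSE	NA	FALSE
prot_0080	FALSE	NA	FALSE
prot_0081	FALSE	NA	FALSE
prot_0082	FALSE	NA	FALSE
prot_0083	FALSE	NA	FALSE
prot_0084	FALSE	NA	FALSE
prot_0085	FALSE	NA	FALSE
prot_0086	FALSE	NA	FALSE
prot_0087	FALSE	NA	FALSE
prot_0088	FALSE	NA	FALSE
prot_0089	FALSE	NA	FALSE
prot_0090	FALSE	NA	FALSE
prot_0091	FALSE	NA	FALSE
prot_0092	FALSE	NA	FALSE
prot_0093	FALSE	NA	FALSE
prot_0094	FALSE	NA	FALSE
prot_0095	FALSE	NA	FALSE
prot_0096	FALSE	NA	FALSE
prot_0097	FALSE	NA	FALSE
prot_0098	FALSE	NA	FALSE
prot_0099	FALSE	NA	FALSE
prot_0100	FALSE	NA	FALSE
prot_0101	FALSE	NA	FALSE
prot_0102	FALSE	NA	FALSE
prot_0103	FALSE	NA	FALSE
prot_0104	FALSE	NA	FALSE
prot_0105	FALSE	NA	FALSE
prot_0106	TRUE	down	TRUE
prot_0107	FALSE	NA	FALSE
prot_0108	FALSE	NA	FALSE
prot_0109	FALSE	NA	FALSE
prot_0110	FALSE	NA	FALSE
prot_0111	FALSE	NA	FALSE
prot_0112	FALSE	NA	FALSE
prot_0113	FALSE	NA	FALSE
prot_0114	TRUE	up	TRUE
prot_0115	FALSE	NA	FALSE
prot_0116	TRUE	up	FALSE
prot_0117	FALSE	NA	FALSE
prot_0118	FALSE	NA	FALSE
prot_0119	TRUE	up	TRUE
prot_0120	FALSE	NA	FALSE
prot_0121	FALSE	NA	FALSE
prot_0122	FALSE	NA	FALSE
prot_0123	FALSE	NA	FALSE
prot_0124	FALSE	NA	FALSE
prot_0125	FALSE	NA	FALSE
prot_0126	FALSE	NA	FALSE
prot_0127	FALSE	NA	FALSE
prot_0128	FALSE	NA	FALSE
prot_0129	FALSE	NA	FALSE
prot_0130	FALSE	NA	FALSE
prot_0131	FALSE	NA	FALSE
prot_0132	FALSE	NA	FALSE
prot_0133	FALSE	NA	FALSE
prot_0134	FALSE	NA	FALSE
prot_0135	TRUE	up	FALSE
prot_0136	FALSE	NA	FALSE
prot_0137	FALSE	NA	FALSE
prot_0138	FALSE	NA	FALSE
prot_0139	FALSE	NA	FALSE
prot_0140	FALSE	NA	FALSE
prot_0141	FALSE	NA	FALSE
prot_0142	FALSE	NA	FALSE
prot_0143	FALSE	NA	FALSE
prot_0144	FALSE	NA	FALSE
prot_0145	FALSE	NA	FALSE
prot_0146	FALSE	NA	FALSE
prot_0147	FALSE	NA	FALSE
prot_0148	FALSE	NA	FALSE
prot_0149	FALSE	NA	FALSE
prot_0150	FALSE	NA	FALSE
prot_0151	FALSE	NA	FALSE
prot_0152	TRUE	up	FALSE
prot_0153	FALSE	NA	FALSE
prot_0154	FALSE	NA	FALSE
prot_0155	FALSE	NA	FALSE
prot_0156	FALSE	NA	FALSE
prot_0157	FALSE	NA	FALSE
prot_0158	FALSE	NA	FALSE
prot_0159	FALSE	NA	FALSE
prot_0160	FALSE	NA	FALSE
prot_0161	FALSE	NA	FALSE
prot_0162	FALSE	NA	FALSE
prot_0163	FALSE	NA	FALSE
prot_0164	FALSE	NA	FALSE
prot_0165	FALSE	NA	FALSE
prot_0166	FALSE	NA	FALSE
prot_0167	FALSE	NA	FALSE
prot_0168	TRUE	down	TRUE
prot_0169	FALSE	NA	FALSE
prot_0170	FALSE	NA	FALSE
prot_0171	FALSE	NA	FALSE
prot_0172	FALSE	NA	FALSE
prot_0173	TRUE	down	FALSE
prot_0174	FALSE	NA	FALSE
prot_0175	FALSE	NA	FALSE
prot_0176	FALSE	NA	FALSE
prot_0177	FALSE	NA	FALSE
prot_0178	FALSE	NA	FALSE
prot_0179	FALSE	NA	FALSE
prot_0180	FALSE	NA	FALSE
prot_0181	FALSE	NA	FALSE
prot_0182	FALSE	NA	FALSE
prot_0183	FALSE	NA	FALSE
prot_0184	FALSE	NA	FALSE
prot_0185	FALSE	NA	FALSE
prot_0186	FALSE	NA	FALSE
prot_0187	FALSE	NA	FALSE
prot_0188	TRUE	down	TRUE
prot_0189	FALSE	NA	FALSE
prot_0190	FALSE	NA	FALSE
prot_0191	FALSE	NA	FALSE
prot_0192	FALSE	NA	FALSE
prot_0193	FALSE	NA	FALSE
prot_0194	FALSE	NA	FALSE
prot_0195	FALSE	NA	FALSE
prot_0196	FALSE	NA	FALSE
prot_0197	FALSE	NA	FALSE
prot_0198	FALSE	NA	FALSE
prot_0199	FALSE	NA	FALSE
prot_0200	FALSE	NA	FALSE
prot_0201	FALSE	NA	FALSE
prot_0202	FALSE	NA	FALSE
prot_0203	TRUE	up	FALSE
prot_0204	FALSE	NA	FALSE
prot_0205	FALSE	NA	FALSE
prot_0206	FALSE	NA	FALSE
prot_0207	FALSE	NA	FALSE
prot_0208	TRUE	down	FALSE
prot_0209	FALSE	NA	FALSE
prot_0210	TRUE	up	TRUE
prot_0211	FALSE	NA	FALSE
prot_0212	FALSE	NA	FALSE
prot_0213	FALSE	NA	FALSE
prot_0214	FALSE	NA	FALSE
prot_0215	FALSE	NA	FALSE
prot_0216	FALSE	NA	FALSE
prot_0217	FALSE	NA	FALSE
prot_0218	FALSE	NA	FALSE
prot_0219	FALSE	NA	FALSE
prot_0220	FALSE	NA	FALSE
prot_0221	TRUE	up	FALSE
prot_0222	FALSE	NA	FALSE
prot_0223	FALSE	NA	FALSE
prot_0224	FALSE	NA	FALSE
prot_0225	TRUE	up	TRUE
prot_0226	FALSE	NA	FALSE
prot_0227	FALSE	NA	FALSE
prot_0228	FALSE	NA	FALSE
prot_0229	FALSE	NA	FALSE
prot_0230	FALSE	NA	FALSE
prot_0231	FALSE	NA	FALSE
prot_0232	FALSE	NA	FALSE
prot_0233	TRUE	down	TRUE
prot_0234	FALSE	NA	FALSE
prot_0235	FALSE	NA	FALSE
prot_0236	TRUE	down	FALSE
prot_0237	FALSE	NA	FALSE
prot_0238	FALSE	NA	FALSE
prot_0239	FALSE	NA	FALSE
prot_0240	FALSE	NA	FALSE
prot_0241	TRUE	down	TRUE
prot_0242	FALSE	NA	FALSE
prot_0243	FALSE	NA	FALSE
prot_0244	FALSE	NA	FALSE
prot_0245	TRUE	down	FALSE
prot_0246	FALSE	NA	FALSE
prot_0247	FALSE	NA	FALSE
prot_0248	FALSE	NA	FALSE
prot_0249	FALSE	NA	FALSE
prot_0250	TRUE	down	TRUE
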