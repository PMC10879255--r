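INFLAMMATORY_RESPONSE_LIKE	immune/inflammatory program (planted up in group 1)	gene_0001	gene_0002	gene_0003	gene_0004	gene_0005	gene_0006	gene_0007	gene_0008	gene_0009	gene_0010	gene_0011	gene_0012	gene_0013	gene_0014	gene_0015	gene_0016	gene_0017	gene_0018	gene_0019	gene_0020	gene_0021	gene_0022	gene_0023	gene_0024	gene_0025	gene_0026	gene_0027	gene_0028	gene_0029	gene_0030	gene_0031	gene_0032	gene_0033	gene_0034	gene_0035	gene_0036	gene_0037	gene_0038	gene_0039	gene_0040	gene_0041	gene_0042	gene_0043	gene_0044	gene_0045	gene_0046	gene_0047	gene_0048	gene_0049	gene_0050	gene_0051	gene_0052	gene_0053	gene_0054	gene_0055	gene_0056	gene_0057	gene_0058	gene_0059	gene_0060	gene_0061	gene_0062	gene_0063	gene_0064	gene_0065	gene_0066	gene_0067	gene_0068	gene_0069	gene_0070	gene_0071	gene_0072	gene_0073	gene_0074	gene_0075	gene_0076	gene_0077	gene_0078	gene_0079	gene_0080	gene_0081	gene_0082	gene_0083	gene_0084	gene_0085	gene_0086	gene_0087	gene_0088	gene_0089	gene_0090	gene_0091	gene_0092	gene_0093	gene_0094	gene_0095	gene_0096	gene_0097	gene_0098	gene_0099	gene_0100
PROLIFERATION_FOXM1_LIKE	cell-cycle/FOXM1-like proliferation program (planted up in the HMR-enriched group; contains the marker genes)	MKI67L	TOP2AL	FOXM1L	gene_0204	gene_0205	gene_0206	gene_0207	gene_0208	gene_0209	gene_0210	gene_0211	gene_0212	gene_0213	gene_0214	gene_0215	gene_0216	gene_0217	gene_0218	gene_0219	gene_0220	gene_0221	gene_0222	gene_0223	gene_0224	gene_0225	gene_0226	gene_0227	gene_0228	gene_0229	gene_0230	gene_0231	gene_0232	gene_0233	gene_0234	gene_0235	gene_0236	gene_0237	gene_0238	gene_0239	gene_0240	gene_0241	gene_0242	gene_0243	gene_0244	gene_0245	gene_0246	gene_0247	gene_0248	gene_0249	gene_0250	gene_0251	gene_0252	gene_0253	gene_0254	gene_0255	gene_0256	gene_0257	gene_0258	gene_0259	gene_0260	gene_0261	gene_0262	gene_0263	gene_0264	gene_0265	gene_0266	gene_0267	gene_0268	gene_0269	gene_0270	gene_0271	gene_0272	gene_0273	gene_0274	gene_0275	gene_0276	gene_0277	gene_0278	gene_0279	gene_0280	gene_0281	gene_0282	gene_0283	gene_0284	gene_0285	gene_0286	gene_0287	gene_0288	gene_0289	gene_0290	gene_0291	gene_0292	gene_0293	gene_0294	gene_0295	gene_0296	gene_0297	gene_0298	gene_0299	gene_0300
HEDGEHOG_SIGNALING_LIKE	Hedgehog-target-like program (planted up in group 3)	gene_0401	gene_0402	gene_0403	gene_0404	gene_0405	gene_0406	gene_0407	gene_0408	gene_0409	gene_0410	gene_0411	gene_0412	gene_0413	gene_0414	gene_0415	gene_0416	gene_0417	gene_0418	gene_0419	gene_0420	gene_0421	gene_0422	gene_0423	gene_0424	gene_0425	gene_0426	gene_0427	gene_0428	gene_0429	gene_0430	gene_0431	gene_0432	gene_0433	gene_0434	gene_0435	gene_0436	gene_0437	gene_0438	gene_0439	gene_0440	gene_0441	gene_0442	gene_0443	gene_0444	gene_0445	gene_0446	gene_0447	gene_0448	gene_0449	gene_0450	gene_0451	gene_0452	gene_0453	gene_0454	gene_0455	gene_0456	gene_0457	gene_0458	gene_0459	gene_0460	gene_0461	gene_0462	gene_0463	gene_0464	gene_0465	gene_0466	gene_0467	gene_0468	gene_0469	gene_0470	gene_0471	gene_0472	gene_0473	gene_0474	gene_0475	gene_0476	gene_0477	gene_0478	gene_0479	gene_0480	gene_0481	gene_0482	gene_0483	gene_0484	gene_0485	gene_0486	gene_0487	gene_0488	gene_0489	gene_0490	gene_0491	gene_0492	gene_0493	gene_0494	gene_0495	gene_0496	gene_0497	gene_0498	gene_0499	gene_0500
RIBOSOME_LIKE	unrelated filler set	gene_1001	gene_1002	gene_1003	gene_1004	gene_1005	gene_1006	gene_1007	gene_1008	gene_1009	gene_1010	gene_1011	gene_1012	gene_1013	gene_1014	gene_1015	gene_1016	gene_1017	gene_1018	gene_1019	gene_1020	gene_1021	gene_1022	gene_1023	gene_1024	gene_1025	gene_1026	gene_1027	gene_1028	gene_1029	gene_1030	gene_1031	gene_1032	gene_1033	gene_1034	gene_1035	gene_1036	gene_1037	gene_1038	gene_1039	gene_1040	gene_1041	gene_1042	gene_1043	gene_1044	gene_1045	gene_1046	gene_1047	gene_1048	gene_1049	gene_1050	gene_1051	gene_1052	gene_1053	gene_1054	gene_1055	gene_1056	gene_1057	gene_1058	gene_1059	gene_1060	gene_1061	gene_1062	gene_1063	gene_1064	gene_1065	gene_1066	gene_1067	gene_1068	gene_1069	gene_1070	gene_1071	gene_1072	gene_1073	gene_1074	gene_1075	gene_1076	gene_1077	gene_1078	gene_1079	gene_1080
METABOLISM_LIKE	unrelated filler set	gene_2001	gene_2002	gene_2003	gene_2004	gene_2005	gene_2006	gene_2007	gene_2008	gene_2009	gene_2010	gene_2011	gene_2012	gene_2013	gene_2014	gene_2015	gene_2016	gene_2017	gene_2018	gene_2019	gene_2020	gene_2021	gene_2022	gene_2023	gene_2024	gene_2025	gene_2026	gene_2027	gene_2028	gene_2029	gene_2030	gene_2031	gene_2032	gene_2033	gene_2034	gene_2035	gene_2036	gene_2037	gene_2038	gene_2039	gene_2040	gene_2041	gene_2042	gene_2043	gene_2044	gene_2045	gene_2046	gene_2047	gene_2048	gene_2049	gene_2050	gene_2051	gene_2052	gene_2053	gene_2054	gene_2055	gene_2056	gene_2057	gene_2058	gene_2059	gene_2060
HOUSEKEEPING_LIKE	unrelated filler set	gene_3001	gene_3002	gene_3003	gene_3004	gene_3005	gene_3006	gene_3007	gene_3008	gene_3009	gene_3010	gene_3011	gene_3012	gene_3013	gene_3014	gene_3015	gene_3016	gene_3017	gene_3018	gene_3019	gene_3020	gene_3021	gene_3022	gene_3023	gene_3024	gene_3025	gene_3026	gene_3027	gene_3028	gene_3029	gene_3030	gene_3031	gene_3032	gene_3033	gene_3034	gene_3035	gene_3036	gene_3037	gene_3038	gene_3039	gene_3040	gene_3041	gene_3042	gene_3043	gene_3044	gene_3045	gene_3046	gene_3047	gene_3048	gene_3049	gene_3050	gene_3051	gene_3052	gene_3053	gene_3054	gene_3055	gene_3056	gene_3057	gene_3058	gene_3059	gene_3060	gene_3061	gene_3062	gene_3063	gene_3064	gene_3065	gene_3066	gene_3067	gene_3068	gene_3069	gene_3070	gene_3071	gene_3072	gene_3073	gene_3074	gene_3075	gene_3076	gene_3077	gene_3078	gene_3079	gene_3080	gene_3081	gene_3082	gene_3083	gene_3084	gene_3085	gene_3086	gene_3087	gene_3088	gene_3089	gene_3090	gene_3091	gene_3092	gene_3093	gene_3094	gene_3095	gene_3096	gene_3097	gene_3098	gene_3099	gene_3100
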