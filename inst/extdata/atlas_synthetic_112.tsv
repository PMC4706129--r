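label	x	y	z	tag
ctx_parietal_R_001	9.22	-18	65.63	parietal
ctx_parietal_L_002	-11.72	-4.41	64.49	parietal
ctx_parietal_R_003	1.78	-43.74	63.34	parietal
ctx_parietal_R_004	14.62	6.13	62.2	parietal
ctx_parietal_L_005	-26.69	-23.98	61.05	parietal
ctx_parietal_R_006	25.15	-38.25	59.91	parietal
ctx_frontal_L_007	-8.37	21.4	58.77	frontal
ctx_parietal_L_008	-15.87	-56.68	57.62	parietal
ctx_parietal_R_009	34.25	-2.17	56.48	parietal
ctx_parietal_L_010	-35.44	0.51	55.33	parietal
ctx_parietal_R_011	16.99	-63.95	54.19	parietal
ctx_frontal_R_012	12.48	32.37	53.05	frontal
ctx_parietal_L_013	-37.41	-45.44	51.9	parietal
ctx_parietal_R_014	43.64	-30.14	50.76	parietal
ctx_frontal_L_015	-26.48	29.67	49.61	frontal
ctx_parietal_L_016	-6.08	-77.39	48.47	parietal
ctx_frontal_R_017	37.11	21.58	47.33	frontal
ctx_parietal_L_018	-49.64	-15.4	46.18	parietal
ctx_parietal_R_019	35.99	-63.32	45.04	parietal
ctx_frontal_L_020	-2.39	47.49	43.89	frontal
ctx_parietal_L_021	-33.82	-69.29	42.75	parietal
ctx_parietal_R_022	53.24	-8.93	41.61	parietal
ctx_frontal_L_023	-44.82	21.47	40.46	frontal
ctx_occipital_R_024	12.17	-86.45	39.32	occipital
ctx_frontal_R_025	27.96	43.75	38.17	frontal
ctx_parietal_L_026	-54.29	-39.92	37.03	parietal
ctx_parietal_R_027	52.38	-48.63	35.89	parietal
ctx_frontal_L_028	-22.54	50.16	34.74	frontal
ctx_occipital_L_029	-19.98	-88.29	33.6	occipital
ctx_frontal_R_030	52.78	17.11	32.45	frontal
ctx_parietal_L_031	-58.21	1.42	31.31	parietal
ctx_occipital_R_032	32.85	-82.66	30.17	occipital
ctx_frontal_R_033	10.37	58.39	29.02	frontal
ctx_parietal_L_034	-48.79	-65.82	27.88	parietal
ctx_parietal_R_035	61.94	-24.49	26.73	parietal
ctx_frontal_L_036	-42.49	40.13	25.59	frontal
ctx_occipital_R_037	0.31	-97.67	24.44	occipital
ctx_frontal_R_038	42.53	41.34	23.3	frontal
ctx_parietal_L_039	-63.35	-25.43	22.16	parietal
ctx_parietal_R_040	50.91	-66.91	21.01	parietal
ctx_frontal_L_041	-11.49	61.92	19.87	frontal
ctx_occipital_L_042	-34.31	-87.01	18.72	occipital
ctx_parietal_R_043	62.34	3.62	17.58	parietal
ctx_frontal_L_044	-57.67	19.46	16.44	frontal
ctx_occipital_R_045	22.59	-95.11	15.29	occipital
ctx_frontal_R_046	24.55	58.32	14.15	frontal
ctx_parietal_L_047	-58.93	-53.35	13	parietal
ctx_parietal_R_048	62.4	-42.35	11.86	parietal
ctx_frontal_L_049	-33.04	53.35	10.72	frontal
ctx_occipital_L_050	-13.72	-98.89	9.57	occipital
ctx_frontal_R_051	53.29	29.91	8.43	frontal
ctx_temporal_L_052	-64.84	-7.77	7.28	temporal
ctx_occipital_R_053	42.32	-80.93	6.14	occipital
ctx_frontal_R_054	2.38	64.48	5	frontal
ctx_temporal_L_055	-45.7	-76.69	3.85	temporal
ctx_temporal_R_056	64.89	-13.8	2.71	temporal
ctx_frontal_L_057	-49.97	34.25	1.56	frontal
ctx_occipital_R_058	8.93	-99.02	0.42	occipital
ctx_frontal_R_059	36.54	49.16	-0.72	frontal
ctx_temporal_L_060	-62.55	-36.22	-1.87	temporal
ctx_temporal_R_061	55.61	-57.88	-3.01	temporal
ctx_frontal_L_062	-19.63	58.59	-4.16	frontal
ctx_occipital_L_063	-26.27	-90.89	-5.3	occipital
ctx_frontal_R_064	57.95	13.11	-6.44	frontal
ctx_frontal_L_065	-58.98	8.44	-7.59	frontal
ctx_occipital_R_066	29.18	-87.45	-8.73	occipital
ctx_frontal_R_067	15.44	57.62	-9.88	frontal
ctx_temporal_L_068	-51.35	-60.24	-11.02	temporal
ctx_temporal_R_069	59.91	-30.65	-12.17	temporal
ctx_frontal_L_070	-37.09	42.01	-13.31	frontal
ctx_occipital_L_071	-4.63	-93.24	-14.45	occipital
ctx_frontal_R_072	43.13	32.99	-15.6	frontal
ctx_temporal_L_073	-58.38	-18.72	-16.74	temporal
ctx_temporal_R_074	42.93	-66.8	-17.89	temporal
ctx_frontal_L_075	-5.54	53.79	-19.03	frontal
ctx_temporal_L_076	-33.78	-74.9	-20.17	temporal
ctx_temporal_R_077	54.49	-5.11	-21.32	temporal
ctx_frontal_L_078	-46.35	18.52	-22.46	frontal
ctx_occipital_R_079	14.45	-83.48	-23.61	occipital
ctx_frontal_R_080	23.87	41.58	-24.75	frontal
ctx_temporal_L_081	-48.48	-41.09	-25.89	temporal
ctx_temporal_R_082	47.12	-41.94	-27.04	temporal
ctx_frontal_L_083	-21.5	38.69	-28.18	frontal
ctx_parietal_L_084	-14.07	-76.78	-29.33	parietal
ctx_frontal_R_085	40.71	12.53	-30.47	frontal
ctx_temporal_L_086	-45.06	-6.04	-31.61	temporal
ctx_parietal_R_087	26.05	-63.94	-32.76	parietal
ctx_frontal_R_088	5.14	36.34	-33.9	frontal
ctx_temporal_L_089	-31.63	-52.41	-35.05	temporal
ctx_temporal_R_090	40.06	-19.6	-36.19	temporal
ctx_frontal_L_091	-27.44	15.89	-37.33	frontal
ctx_parietal_R_092	2.04	-64.08	-38.48	parietal
ctx_frontal_R_093	21.81	15.74	-39.62	frontal
ctx_temporal_L_094	-31.9	-23.83	-40.77	temporal
ctx_parietal_R_095	24.63	-39.24	-41.91	parietal
ctx_frontal_L_096	-6.21	15.39	-43.05	frontal
ctx_parietal_L_097	-11.74	-44.53	-44.2	parietal
ctx_parietal_R_098	19.39	-9.91	-45.34	parietal
ctx_parietal_L_099	-14.49	-9.74	-46.49	parietal
ctx_parietal_R_100	3.64	-28.72	-47.63	parietal
thalamus_R	10	-37	16	subcortical
thalamus_L	-10	-37	16	subcortical
caudate_R	13	-8	19	subcortical
caudate_L	-13	-8	19	subcortical
putamen_R	26	-18	10	subcortical
putamen_L	-26	-18	10	subcortical
pallidum_R	23.8	-19.4	8.95	subcortical
pallidum_L	-23.8	-19.4	8.95	subcortical
hippocampus_R	26	-40	-5	subcortical
hippocampus_L	-26	-40	-5	subcortical
amygdala_R	24	-22	-9	subcortical
amygdala_L	-24	-22	-9	subcortical
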