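gene_id	cancer_type	cancer_subtype	study_id	direction	p_value	fold_change	percentile
KCNK1	Brain	Glioblastoma	A001	under	1.72E-24	-9.574	2
KCNK1	Brain	Glioblastoma	A002	under	1.80E-14	-20.541	3
KCNK1	Brain	Glioblastoma	A003	under	1.07E-08	-8.483	3
KCNK1	Brain	Glioblastoma	A004	under	1.03E-05	-13.309	4
KCNK1	Brain	Glioblastoma	A005	over	5.89E-04	3.178	6
KCNK1	Breast	Ductal	A006	over	5.23E-04	2.515	5
KCNK1	Breast	Ductal	A007	over	7.18E-04	3.965	5
KCNK1	Breast	Ductal	A008	over	1.00E-03	2.405	5
KCNK1	Breast	Ductal	A009	over	4.00E-03	2.661	9
KCNK1	Breast	Ductal	A010	over	1.10E-02	2.4	9
KCNK1	Breast	Lobular	A011	over	2.20E-02	2.177	4
KCNK1	Cervical	Squamous cell	A012	over	9.70E-13	2.949	1
KCNK1	Leukaemia	Acute lymphocytic	A013	over	4.00E-03	2.173	5
KCNK1	Lung	Adenocarcinoma	A014	over	3.59E-07	3.984	2
KCNK1	Lung	Adenocarcinoma	A015	over	5.38E-07	2.141	3
KCNK1	Lung	Adenocarcinoma	A016	over	2.35E-05	4.641	1
KCNK1	Lung	Adenocarcinoma	A017	over	6.21E-05	2.137	8
KCNK1	Lung	Squamous cell	A018	over	5.98E-08	2.138	9
KCNK1	Lung	Squamous cell	A019	over	2.61E-06	7.79	2
KCNK1	Pancreas	Adenocarcinoma	A020	over	9.83E-10	3.526	5
KCNK1	Pancreas	Adenocarcinoma	A021	over	2.61E-04	6.584	3
KCNK1	Pancreas	Adenocarcinoma	A022	over	1.41E-04	6.62	5
KCNK1	Pancreas	Adenocarcinoma	A023	over	1.21E-08	4.613	1
KCNK1	Pancreas	Adenocarcinoma	A024	over	2.00E-03	2.685	9
KCNK6	Breast	Ductal	A025	over	2.77E-19	2.161	9
KCNK6	Breast	Ductal	A026	over	1.00E-03	2.765	1
KCNK6	Colorectal	Adenocarcinoma	A027	under	1.77E-18	-2.071	4
KCNK6	Colorectal	Adenocarcinoma	A028	under	2.38E-15	-2.11	7
KCNK6	Colorectal	Adenocarcinoma	A029	under	9.37E-15	-2.136	1
KCNK7	Cervical	Squamous cell	A030	under	5.62E-10	-6.76	1
KCNK7	Cervical	Squamous cell	A031	under	1.86E-08	-3.055	1
KCNK7	Cervical	Squamous cell	A032	under	7.99E-04	-3.315	5
KCNK7	Gastrointestinal	Adenocarcinoma	A033	under	1.60E-02	-2.336	10
KCNK2	Breast	Invasive	A034	under	5.70E-05	-2.23	4
KCNK2	Lung	Squamous cell	A035	over	2.98E-04	2.111	5
KCNK10	Brain	Glioblastoma	A036	under	1.81E-17	-4.843	5
KCNK10	Brain	Glioblastoma	A037	under	1.56E-10	-2.974	6
KCNK10	Brain	Glioblastoma	A038	over	8.63E-04	2.547	7
KCNK10	Breast	Ductal	A039	under	1.00E-03	-2.294	2
KCNK10	Breast	Ductal	A040	under	3.85E-04	-3.523	2
KCNK10	Colorectal	Adenocarcinoma	A041	under	1.74E-25	-7.227	1
KCNK10	Colorectal	Adenocarcinoma	A042	under	3.19E-22	-7.914	2
KCNK10	Colorectal	Adenocarcinoma	A043	under	2.85E-18	-6.275	1
KCNK10	Colorectal	Adenocarcinoma	A044	under	2.07E-14	-4.83	2
KCNK10	Colorectal	Adenocarcinoma	A045	under	1.11E-07	-6.275	2
KCNK10	Colorectal	Adenocarcinoma	A046	under	3.42E-07	-2.503	3
KCNK3	Brain	Glioblastoma	A047	under	6.20E-08	-5.468	10
KCNK3	Brain	Glioblastoma	A048	under	2.61E-05	-4.471	3
KCNK3	Breast	Invasive	A049	over	4.41E-17	2.782	4
KCNK3	Breast	Invasive	A050	over	1.50E-02	2.958	6
KCNK3	Breast	Invasive	A051	under	1.00E-03	-2.375	7
KCNK3	Colorectal	Adenoma	A052	under	2.37E-04	-2.493	10
KCNK3	Colorectal	Adenoma	A053	under	2.00E-03	-4.175	5
KCNK3	Gastrointestinal	Adenocarcinoma	A054	over	2.85E-04	3.567	6
KCNK3	Kidney	Clear cell	A055	over	1.53E-14	8.407	1
KCNK3	Kidney	Clear cell	A056	over	2.57E-07	6.014	5
KCNK3	Kidney	Clear cell	A057	over	4.01E-05	4.541	7
KCNK3	Kidney	Clear cell	A058	over	1.89E-04	6.344	6
KCNK3	Leukaemia	Acute lymphocytic	A059	over	1.30E-02	2.177	9
KCNK3	Lung	Adenocarcinoma	A060	under	6.55E-34	-4.136	1
KCNK3	Lung	Adenocarcinoma	A061	under	8.44E-20	-6.89	1
KCNK3	Lung	Adenocarcinoma	A062	under	8.67E-11	-7.375	2
KCNK3	Lung	Adenocarcinoma	A063	under	4.11E-10	-2.367	1
KCNK3	Lung	Adenocarcinoma	A064	under	2.54E-06	-7.399	3
KCNK3	Lung	Adenocarcinoma	A065	under	1.08E-04	-3.803	4
KCNK3	Lung	Squamous cell	A066	under	5.90E-20	-12.756	2
KCNK3	Lung	Squamous cell	A067	under	3.86E-06	-8.471	3
KCNK3	Lung	Squamous cell	A068	under	1.58E-05	-4.28	3
KCNK3	Lung	Squamous cell	A069	under	2.00E-03	-2.422	7
KCNK3	Pancreas	Adenocarcinoma	A070	under	7.34E-06	-6.459	1
KCNK3	Pancreas	Adenocarcinoma	A071	under	4.72E-05	-5.03	1
KCNK3	Pancreas	Adenocarcinoma	A072	under	1.19E-04	-2.191	3
KCNK3	Prostate	Carcinoma	A073	under	2.72E-08	-2.034	3
KCNK3	Prostate	Carcinoma	A074	under	1.02E-04	-2.638	2
KCNK3	Prostate	Carcinoma	A075	under	8.94E-04	-3.106	4
KCNK9	Breast	Invasive	A076	over	1.16E-12	3.95	9
KCNK15	Breast	Ductal	A077	over	1.00E-03	5.046	6
KCNK15	Breast	Ductal	A078	over	8.00E-03	2.283	9
KCNK15	Breast	Ductal	A079	over	4.10E-02	8.774	8
KCNK15	Gastrointestinal	Adenocarcinoma	A080	under	3.00E-03	-2.189	5
KCNK5	Breast	Ductal	A081	over	2.14E-04	2.977	3
KCNK5	Breast	Ductal	A082	under	7.70E-04	-3.629	4
KCNK5	Breast	Ductal	A083	under	2.00E-03	-2.498	2
KCNK5	Breast	Ductal	A084	under	1.00E-03	-3.856	6
KCNK5	Colorectal	Adenocarcinoma	A085	under	2.42E-12	-3.18	3
KCNK5	Colorectal	Adenocarcinoma	A086	under	1.95E-11	-2.498	5
KCNK5	Colorectal	Adenocarcinoma	A087	under	7.86E-08	-3.199	2
KCNK17	Breast	Invasive	A088	over	2.20E-02	3.265	8
KCNK13	Breast	Invasive	A089	over	3.35E-12	3.193	10
KCNK13	Breast	Invasive	A090	over	4.99E-08	2.05	10
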