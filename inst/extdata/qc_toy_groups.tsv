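id	diabetes
id00001	0
id00002	0
id00003	0
id00004	0
id00005	0
id00006	0
id00007	0
id00008	0
id00009	0
id00010	0
id00011	0
id00012	0
id00013	0
id00014	0
id00015	0
id00016	0
id00017	0
id00018	0
id00019	0
id00020	0
id00021	0
id00022	0
id00023	0
id00024	0
id00025	0
id00026	0
id00027	0
id00028	0
id00029	0
id00030	0
id00031	0
id00032	0
id00033	0
id00034	0
id00035	0
id00036	0
id00037	0
id00038	0
id00039	0
id00040	0
id00041	0
id00042	0
id00043	0
id00044	0
id00045	0
id00046	0
id00047	0
id00048	0
id00049	0
id00050	0
id00051	0
id00052	0
id00053	0
id00054	0
id00055	0
id00056	0
id00057	0
id00058	0
id00059	0
id00060	0
id00061	0
id00062	0
id00063	0
id00064	0
id00065	0
id00066	0
id00067	0
id00068	0
id00069	0
id00070	0
id00071	0
id00072	0
id00073	0
id00074	0
id00075	0
id00076	0
id00077	0
id00078	0
id00079	0
id00080	0
id00081	0
id00082	0
id00083	0
id00084	0
id00085	0
id00086	0
id00087	0
id00088	0
id00089	0
id00090	0
id00091	0
id00092	0
id00093	0
id00094	0
id00095	0
id00096	0
id00097	0
id00098	0
id00099	0
id00100	0
id00101	1
id00102	1
id00103	1
id00104	1
id00105	1
id00106	1
id00107	1
id00108	1
id00109	1
id00110	1
id00111	1
id00112	1
id00113	1
id00114	1
id00115	1
id00116	1
id00117	1
id00118	1
id00119	1
id00120	1
id00121	1
id00122	1
id00123	1
id00124	1
id00125	1
id00126	1
id00127	1
id00128	1
id00129	1
id00130	1
id00131	1
id00132	1
id00133	1
id00134	1
id00135	1
id00136	1
id00137	1
id00138	1
id00139	1
id00140	1
id00141	1
id00142	1
id00143	1
id00144	1
id00145	1
id00146	1
id00147	1
id00148	1
id00149	1
id00150	1
id00151	1
id00152	1
id00153	1
id00154	1
id00155	1
id00156	1
id00157	1
id00158	1
id00159	1
id00160	1
id00161	1
id00162	1
id00163	1
id00164	1
id00165	1
id00166	1
id00167	1
id00168	1
id00169	1
id00170	1
id00171	1
id00172	1
id00173	1
id00174	1
id00175	1
id00176	1
id00177	1
id00178	1
id00179	1
id00180	1
id00181	1
id00182	1
id00183	1
id00184	1
id00185	1
id00186	1
id00187	1
id00188	1
id00189	1
id00190	1
id00191	1
id00192	1
id00193	1
id00194	1
id00195	1
id00196	1
id00197	1
id00198	1
id00199	1
id00200	1
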