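id	mk_at	mk_rare	mk_hwe	mk_ok1	mk_ok2
id00001	2	1	1	2	2
id00002	2	0	1	2	2
id00003	2	0	1	2	2
id00004	2	0	1	2	2
id00005	2	0	1	2	2
id00006	2	0	1	2	2
id00007	2	0	1	2	2
id00008	2	0	1	2	2
id00009	2	0	1	2	2
id00010	1	0	1	1	2
id00011	1	0	1	1	2
id00012	1	0	1	1	2
id00013	1	0	1	1	2
id00014	1	0	1	1	2
id00015	1	0	1	1	2
id00016	1	0	1	1	2
id00017	1	0	1	1	1
id00018	1	0	1	1	1
id00019	1	0	1	1	1
id00020	1	0	1	1	1
id00021	1	0	1	1	1
id00022	1	0	1	1	1
id00023	1	0	1	1	1
id00024	1	0	1	1	1
id00025	1	0	1	1	1
id00026	1	0	1	1	1
id00027	1	0	1	1	1
id00028	1	0	1	1	1
id00029	1	0	1	1	1
id00030	1	0	1	1	1
id00031	1	0	1	1	1
id00032	1	0	1	1	1
id00033	1	0	1	1	1
id00034	1	0	1	1	1
id00035	1	0	1	1	1
id00036	1	0	1	1	1
id00037	1	0	1	1	1
id00038	1	0	1	1	1
id00039	1	0	1	1	1
id00040	1	0	1	1	1
id00041	1	0	1	1	1
id00042	1	0	1	1	1
id00043	1	0	1	1	1
id00044	1	0	1	1	1
id00045	1	0	1	1	1
id00046	1	0	1	1	1
id00047	1	0	1	1	1
id00048	1	0	1	1	1
id00049	1	0	1	1	1
id00050	1	0	1	1	1
id00051	1	0	1	1	1
id00052	0	0	1	0	1
id00053	0	0	1	0	1
id00054	0	0	1	0	1
id00055	0	0	1	0	1
id00056	0	0	1	0	1
id00057	0	0	1	0	1
id00058	0	0	1	0	1
id00059	0	0	1	0	1
id00060	0	0	1	0	1
id00061	0	0	1	0	1
id00062	0	0	1	0	1
id00063	0	0	1	0	1
id00064	0	0	1	0	1
id00065	0	0	1	0	0
id00066	0	0	1	0	0
id00067	0	0	1	0	0
id00068	0	0	1	0	0
id00069	0	0	1	0	0
id00070	0	0	1	0	0
id00071	0	0	1	0	0
id00072	0	0	1	0	0
id00073	0	0	1	0	0
id00074	0	0	1	0	0
id00075	0	0	1	0	0
id00076	0	0	1	0	0
id00077	0	0	1	0	0
id00078	0	0	1	0	0
id00079	0	0	1	0	0
id00080	0	0	1	0	0
id00081	0	0	1	0	0
id00082	0	0	1	0	0
id00083	0	0	1	0	0
id00084	0	0	1	0	0
id00085	0	0	1	0	0
id00086	0	0	1	0	0
id00087	0	0	1	0	0
id00088	0	0	1	0	0
id00089	0	0	1	0	0
id00090	0	0	1	0	0
id00091	0	0	1	0	0
id00092	0	0	1	0	0
id00093	0	0	1	0	0
id00094	0	0	1	0	0
id00095	0	0	1	0	0
id00096	0	0	1	0	0
id00097	0	0	1	0	0
id00098	0	0	1	0	0
id00099	0	0	1	0	0
id00100	0	0	1	0	0
id00101	2	1	1	2	2
id00102	2	0	1	2	2
id00103	2	0	1	2	2
id00104	2	0	1	2	2
id00105	2	0	1	2	2
id00106	2	0	1	2	2
id00107	2	0	1	2	2
id00108	2	0	1	2	2
id00109	2	0	1	2	2
id00110	1	0	1	1	2
id00111	1	0	1	1	2
id00112	1	0	1	1	2
id00113	1	0	1	1	2
id00114	1	0	1	1	2
id00115	1	0	1	1	2
id00116	1	0	1	1	2
id00117	1	0	1	1	1
id00118	1	0	1	1	1
id00119	1	0	1	1	1
id00120	1	0	1	1	1
id00121	1	0	1	1	1
id00122	1	0	1	1	1
id00123	1	0	1	1	1
id00124	1	0	1	1	1
id00125	1	0	1	1	1
id00126	1	0	1	1	1
id00127	1	0	1	1	1
id00128	1	0	1	1	1
id00129	1	0	1	1	1
id00130	1	0	1	1	1
id00131	1	0	1	1	1
id00132	1	0	1	1	1
id00133	1	0	1	1	1
id00134	1	0	1	1	1
id00135	1	0	1	1	1
id00136	1	0	1	1	1
id00137	1	0	1	1	1
id00138	1	0	1	1	1
id00139	1	0	1	1	1
id00140	1	0	1	1	1
id00141	1	0	1	1	1
id00142	1	0	1	1	1
id00143	1	0	1	1	1
id00144	1	0	1	1	1
id00145	1	0	1	1	1
id00146	1	0	1	1	1
id00147	1	0	1	1	1
id00148	1	0	1	1	1
id00149	1	0	1	1	1
id00150	1	0	1	1	1
id00151	1	0	1	1	1
id00152	0	0	1	0	1
id00153	0	0	1	0	1
id00154	0	0	1	0	1
id00155	0	0	1	0	1
id00156	0	0	1	0	1
id00157	0	0	1	0	1
id00158	0	0	1	0	1
id00159	0	0	1	0	1
id00160	0	0	1	0	1
id00161	0	0	1	0	1
id00162	0	0	1	0	1
id00163	0	0	1	0	1
id00164	0	0	1	0	1
id00165	0	0	1	0	0
id00166	0	0	1	0	0
id00167	0	0	1	0	0
id00168	0	0	1	0	0
id00169	0	0	1	0	0
id00170	0	0	1	0	0
id00171	0	0	1	0	0
id00172	0	0	1	0	0
id00173	0	0	1	0	0
id00174	0	0	1	0	0
id00175	0	0	1	0	0
id00176	0	0	1	0	0
id00177	0	0	1	0	0
id00178	0	0	1	0	0
id00179	0	0	1	0	0
id00180	0	0	1	0	0
id00181	0	0	1	0	0
id00182	0	0	1	0	0
id00183	0	0	1	0	0
id00184	0	0	1	0	0
id00185	0	0	1	0	0
id00186	0	0	1	0	0
id00187	0	0	1	0	0
id00188	0	0	1	0	0
id00189	0	0	1	0	0
id00190	0	0	1	0	0
id00191	0	0	1	0	0
id00192	0	0	1	0	0
id00193	0	0	1	0	0
id00194	0	0	1	0	0
id00195	0	0	1	0	0
id00196	0	0	1	0	0
id00197	0	0	1	0	0
id00198	0	0	1	0	0
id00199	0	0	1	0	0
id00200	0	0	1	0	0
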