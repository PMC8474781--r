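#name=epitoc_synthetic
#intercept=0
#calibration=identity
cpg_id	weight
cgS00001	NA
cgS00002	NA
cgS00003	NA
cgS00004	NA
cgS00005	NA
cgS00006	NA
cgS00007	NA
cgS00008	NA
cgS00009	NA
cgS00010	NA
cgS00011	NA
cgS00012	NA
cgS00013	NA
cgS00014	NA
cgS00015	NA
cgS00016	NA
cgS00017	NA
cgS00018	NA
cgS00019	NA
cgS00020	NA
cgS00021	NA
cgS00022	NA
cgS00023	NA
cgS00024	NA
cgS00025	NA
cgS00026	NA
cgS00027	NA
cgS00028	NA
cgS00029	NA
cgS00030	NA
cgS00031	NA
cgS00032	NA
cgS00033	NA
cgS00034	NA
cgS00035	NA
cgS00036	NA
cgS00037	NA
cgS00038	NA
cgS00039	NA
cgS00040	NA
cgS00041	NA
cgS00042	NA
cgS00043	NA
cgS00044	NA
cgS00045	NA
cgS00046	NA
cgS00047	NA
cgS00048	NA
cgS00049	NA
cgS00050	NA
cgS00051	NA
cgS00052	NA
cgS00053	NA
cgS00054	NA
cgS00055	NA
cgS00056	NA
cgS00057	NA
cgS00058	NA
cgS00059	NA
cgS00060	NA
cgS00061	NA
cgS00062	NA
cgS00063	NA
cgS00064	NA
cgS00065	NA
cgS00066	NA
cgS00067	NA
cgS00068	NA
cgS00069	NA
cgS00070	NA
cgS00071	NA
cgS00072	NA
cgS00073	NA
cgS00074	NA
cgS00075	NA
cgS00076	NA
cgS00077	NA
cgS00078	NA
cgS00079	NA
cgS00080	NA
cgS00081	NA
cgS00082	NA
cgS00083	NA
cgS00084	NA
cgS00085	NA
cgS00086	NA
cgS00087	NA
cgS00088	NA
cgS00089	NA
cgS00090	NA
cgS00091	NA
cgS00092	NA
cgS00093	NA
cgS00094	NA
cgS00095	NA
cgS00096	NA
cgS00097	NA
cgS00098	NA
cgS00099	NA
cgS00100	NA
cgS00101	NA
cgS00102	NA
cgS00103	NA
cgS00104	NA
cgS00105	NA
cgS00106	NA
cgS00107	NA
cgS00108	NA
cgS00109	NA
cgS00110	NA
cgS00111	NA
cgS00112	NA
cgS00113	NA
cgS00114	NA
cgS00115	NA
cgS00116	NA
cgS00117	NA
cgS00118	NA
cgS00119	NA
cgS00120	NA
cgS00121	NA
cgS00122	NA
cgS00123	NA
cgS00124	NA
cgS00125	NA
cgS00126	NA
cgS00127	NA
cgS00128	NA
cgS00129	NA
cgS00130	NA
cgS00131	NA
cgS00132	NA
cgS00133	NA
cgS00134	NA
cgS00135	NA
cgS00136	NA
cgS00137	NA
cgS00138	NA
cgS00139	NA
cgS00140	NA
cgS00141	NA
cgS00142	NA
cgS00143	NA
cgS00144	NA
cgS00145	NA
cgS00146	NA
cgS00147	NA
cgS00148	NA
cgS00149	NA
cgS00150	NA
cgS00151	NA
cgS00152	NA
cgS00153	NA
cgS00154	NA
cgS00155	NA
cgS00156	NA
cgS00157	NA
cgS00158	NA
cgS00159	NA
cgS00160	NA
cgS00161	NA
cgS00162	NA
cgS00163	NA
cgS00164	NA
cgS00165	NA
cgS00166	NA
cgS00167	NA
cgS00168	NA
cgS00169	NA
cgS00170	NA
cgS00171	NA
cgS00172	NA
cgS00173	NA
cgS00174	NA
cgS00175	NA
cgS00176	NA
cgS00177	NA
cgS00178	NA
cgS00179	NA
cgS00180	NA
cgS00181	NA
cgS00182	NA
cgS00183	NA
cgS00184	NA
cgS00185	NA
cgS00186	NA
cgS00187	NA
cgS00188	NA
cgS00189	NA
cgS00190	NA
cgS00191	NA
cgS00192	NA
cgS00193	NA
cgS00194	NA
cgS00195	NA
cgS00196	NA
cgS00197	NA
cgS00198	NA
cgS00199	NA
cgS00200	NA
cgS00201	NA
cgS00202	NA
cgS00203	NA
cgS00204	NA
cgS00205	NA
cgS00206	NA
cgS00207	NA
cgS00208	NA
cgS00209	NA
cgS00210	NA
cgS00211	NA
cgS00212	NA
cgS00213	NA
cgS00214	NA
cgS00215	NA
cgS00216	NA
cgS00217	NA
cgS00218	NA
cgS00219	NA
cgS00220	NA
cgS00221	NA
cgS00222	NA
cgS00223	NA
cgS00224	NA
cgS00225	NA
cgS00226	NA
cgS00227	NA
cgS00228	NA
cgS00229	NA
cgS00230	NA
cgS00231	NA
cgS00232	NA
cgS00233	NA
cgS00234	NA
cgS00235	NA
cgS00236	NA
cgS00237	NA
cgS00238	NA
cgS00239	NA
cgS00240	NA
cgS00241	NA
cgS00242	NA
cgS00243	NA
cgS00244	NA
cgS00245	NA
cgS00246	NA
cgS00247	NA
cgS00248	NA
cgS00249	NA
cgS00250	NA
cgS00251	NA
cgS00252	NA
cgS00253	NA
cgS00254	NA
cgS00255	NA
cgS00256	NA
cgS00257	NA
cgS00258	NA
cgS00259	NA
cgS00260	NA
cgS00261	NA
cgS00262	NA
cgS00263	NA
cgS00264	NA
cgS00265	NA
cgS00266	NA
cgS00267	NA
cgS00268	NA
cgS00269	NA
cgS00270	NA
cgS00271	NA
cgS00272	NA
cgS00273	NA
cgS00274	NA
cgS00275	NA
cgS00276	NA
cgS00277	NA
cgS00278	NA
cgS00279	NA
cgS00280	NA
cgS00281	NA
cgS00282	NA
cgS00283	NA
cgS00284	NA
cgS00285	NA
cgS00286	NA
cgS00287	NA
cgS00288	NA
cgS00289	NA
cgS00290	NA
cgS00291	NA
cgS00292	NA
cgS00293	NA
cgS00294	NA
cgS00295	NA
cgS00296	NA
cgS00297	NA
cgS00298	NA
cgS00299	NA
cgS00300	NA
cgS00301	NA
cgS00302	NA
cgS00303	NA
cgS00304	NA
cgS00305	NA
cgS00306	NA
cgS00307	NA
cgS00308	NA
cgS00309	NA
cgS00310	NA
cgS00311	NA
cgS00312	NA
cgS00313	NA
cgS00314	NA
cgS00315	NA
cgS00316	NA
cgS00317	NA
cgS00318	NA
cgS00319	NA
cgS00320	NA
cgS00321	NA
cgS00322	NA
cgS00323	NA
cgS00324	NA
cgS00325	NA
cgS00326	NA
cgS00327	NA
cgS00328	NA
cgS00329	NA
cgS00330	NA
cgS00331	NA
cgS00332	NA
cgS00333	NA
cgS00334	NA
cgS00335	NA
cgS00336	NA
cgS00337	NA
cgS00338	NA
cgS00339	NA
cgS00340	NA
cgS00341	NA
cgS00342	NA
cgS00343	NA
cgS00344	NA
cgS00345	NA
cgS00346	NA
cgS00347	NA
cgS00348	NA
cgS00349	NA
cgS00350	NA
cgS00351	NA
cgS00352	NA
cgS00353	NA
cgS00354	NA
cgS00355	NA
cgS00356	NA
cgS00357	NA
cgS00358	NA
cgS00359	NA
cgS00360	NA
cgS00361	NA
cgS00362	NA
cgS00363	NA
cgS00364	NA
cgS00365	NA
cgS00366	NA
cgS00367	NA
cgS00368	NA
cgS00369	NA
cgS00370	NA
cgS00371	NA
cgS00372	NA
cgS00373	NA
cgS00374	NA
cgS00375	NA
cgS00376	NA
cgS00377	NA
cgS00378	NA
cgS00379	NA
cgS00380	NA
cgS00381	NA
cgS00382	NA
cgS00383	NA
cgS00384	NA
cgS00385	NA
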