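kmer	shear	buckle	stretch	propeller	stagger	opening
AAA	0.464	-13.466	-0.006	-15.527	-0.477	0.176
AAC	0.025	-3.921	0.107	-11.369	-0.135	1.15
AAG	-0.174	4.776	-0.12	-0.194	0.051	3.543
AAT	-0.306	2.721	-0.033	-3.416	0.418	-3.437
ACA	0.381	2.486	-0.041	-18.723	-0.458	4.223
ACC	-0.438	-2.807	0.18	-4.828	0.324	-4.19
ACG	-0.063	12.986	-0.256	-16.08	-0.106	3.427
ACT	-0.224	13.487	-0.195	3.489	-0.316	-1.256
AGA	0.21	10.493	0.148	-2.422	0.347	3.528
AGC	-0.425	-4.351	0.136	-7.809	-0.308	4.384
AGG	0.198	8.824	-0.029	-4.69	-0.203	3.152
AGT	-0.392	-5.17	-0.291	-6.919	0.017	-3.864
ATA	-0.219	10.67	-0.223	-4.42	-0.484	-0.394
ATC	-0.513	-2.986	0.241	3.188	0.175	2.278
ATG	-0.545	-11.524	-0.189	-12.682	0.353	0.412
ATT	-0.08	4.01	0.197	0.408	-0.003	-3.536
CAA	-0.193	-3.604	0.009	1.109	0.385	-1.151
CAC	0.467	0.984	-0.296	2.937	0.252	3.37
CAG	0.329	13.467	-0.017	-18.646	0.404	-1.642
CAT	0.422	-7.397	-0.021	0.654	-0.324	3.818
CCA	-0.367	11.745	-0.067	-19.955	0.393	2.566
CCC	0.175	12.822	-0.085	-11.379	-0.039	4.543
CCG	0.398	-3.591	0.107	-2.685	0.518	-3.361
CCT	0.398	-3.918	-0.144	-13.301	0.032	4.333
CGA	-0.566	-6.276	0.028	-8.671	0.531	2.612
CGC	0.328	-6.587	-0.272	-12.819	-0.158	-1.059
CGG	-0.507	-11.247	-0.111	-12.971	0.207	1.54
CGT	-0.113	-11.009	0.157	-11.702	-0.096	3.026
CTA	-0.404	10.926	0.229	-19.538	0.193	-1.794
CTC	0.371	8.663	0.045	-12.507	0.496	-2.489
CTG	-0.326	12.017	-0.232	-10.553	-0.193	-0.937
CTT	-0.442	5.971	0.209	-14.124	-0.472	2.674
GAA	0.448	2.821	-0.025	3.751	-0.086	-1.274
GAC	0.407	5.932	0.061	-13.211	0.408	5.08
GAG	0.102	2.202	0.11	-10.66	-0.139	5.408
GAT	0.031	-12.022	-0.134	-9.826	-0.206	-1.197
GCA	-0.283	-1.464	-0.119	-13.605	-0.004	-3.901
GCC	-0.353	10.388	-0.286	-2.323	0.019	5.421
GCG	0.258	13.298	-0.073	1.22	0.374	4.163
GCT	0.223	4.644	-0.041	-14.968	-0.475	0.655
GGA	0.06	12.946	-0.068	-12.997	0.301	0.479
GGC	0.1	9.73	0.105	-4.626	-0.257	2.789
GGG	0.236	-1.355	-0.025	-16.054	0.458	4.716
GGT	0.488	2.321	-0.071	-5.554	-0.42	-2.066
GTA	-0.427	-8.695	0.012	-1.564	0.241	1.172
GTC	0.595	11.956	0.179	1.46	0.39	1.045
GTG	0.275	-10.724	-0.282	-19.451	-0.358	1.712
GTT	0.501	-12.343	-0.204	-16.701	0.319	4.852
TAA	0.328	1.362	0.001	-19.301	0.243	2.931
TAC	0.294	2.208	0.054	-7.455	0.151	-4.383
TAG	-0.573	7.405	0.009	-8.818	0.433	-4.297
TAT	0.077	-11.79	0.192	-19.809	-0.315	-3.698
TCA	-0.173	-4.603	0.025	-7.53	-0.527	3.102
TCC	0.055	8.413	-0.058	3.008	0.394	-0.438
TCG	-0.336	7.404	-0.199	-7.176	0.167	2.881
TCT	-0.119	0.335	-0.044	3.598	0.415	-3.87
TGA	0.352	-9.864	-0.079	-2.112	0.281	2.583
TGC	-0.48	12.023	-0.123	2.967	-0.388	-1.45
TGG	-0.179	9.42	0.134	2.405	-0.036	3.366
TGT	-0.26	1.125	-0.077	-0.89	-0.521	-1.714
TTA	-0.102	-3.511	-0.236	-3.831	0.075	1.693
TTC	0.182	-2.932	-0.226	-12.86	0.276	-0.67
TTG	-0.188	-13.161	0.053	-7.163	-0.286	-4.369
TTT	0.327	2.731	0.161	-0.582	-0.066	-1.914
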