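aa	hb	hw	mass	kd	hb2	hw2	mass2	kd2	hb_hw	hb_mass	hb_kd	hw_mass	hw_kd	mass_kd	hb3	hw3	mass3	kd3	rank_hb	rank_mass	rank_kd
A	0.62014	-0.148032	-1.551628	0.766663	-0.394777	-0.806488	1.072747	-0.436612	0.666633	-0.833268	-0.388677	0.352871	0.681756	-1.60371	0.243962	-0.201396	-1.195969	0.085601	0.591608	-1.437844	0.593845
C	0.290066	-0.407738	-0.516131	1.001014	-0.604539	-0.681062	-0.503132	0.062713	0.641848	0.040607	-0.58893	0.334737	0.315445	-0.438574	0.188076	-0.228487	-0.078143	0.397014	0.253546	-0.592053	0.933185
D	-0.900204	1.669909	-0.127819	-1.00771	-0.097491	1.597702	-0.68717	0.078925	-0.655006	0.325377	0.078424	-0.06467	-1.26913	0.679011	-0.008725	1.754488	-0.036077	-0.745286	-1.267731	0.084579	-1.018019
E	-0.740168	1.669909	0.325211	-1.00771	-0.28078	1.597702	-0.621354	0.078925	-0.404767	-0.057264	-0.096069	0.64815	-1.26913	-0.11144	0.075852	1.754488	-0.024743	-0.745286	-0.760639	0.507474	-1.018019
F	1.190269	-1.186856	0.907678	1.10145	0.325876	0.398538	-0.092824	0.317239	-0.570191	1.363595	0.515415	-0.878609	-0.802296	2.187038	0.621905	-0.901743	0.196895	0.58486	1.436762	1.099528	1.102854
G	0.480109	0.111674	-2.004658	0.030131	-0.502347	-0.814693	2.25851	-1.14399	0.802796	-0.833512	-0.887444	-0.074489	0.827027	0.351407	0.210594	-0.19945	-2.538185	-0.168409	0.422577	-1.607002	0.424175
H	-0.400091	-0.148032	0.616444	-0.907273	-0.551523	-0.806488	-0.419514	-0.152905	0.80805	-0.063634	-0.510343	0.050464	0.989808	-0.512386	0.164987	-0.201396	0.037346	-0.589422	-0.591608	0.930369	-0.593845
I	1.380312	-0.823268	-0.192538	1.670588	0.666958	-0.236562	-0.67191	2.21889	-0.311462	-0.084208	1.591899	0.285801	-0.88693	-0.100935	0.868213	-0.434234	-0.037646	2.459865	1.605793	-0.338316	1.611864
K	-1.50034	1.669909	0.325211	-1.141624	0.908363	1.597702	-0.621354	0.425858	-1.593406	-0.32315	0.950161	0.64815	-1.547133	-0.186846	-0.699916	1.754488	-0.024743	-1.007179	-1.436762	0.507474	-1.442194
L	1.06024	-0.823268	-0.192538	1.436237	0.121562	-0.236562	-0.67191	1.341288	-0.064725	-0.017928	0.744509	0.285801	-0.647082	-0.022809	0.492824	-0.434234	-0.037646	1.501679	1.098701	-0.338316	1.272524
M	0.640145	-0.563562	0.389929	0.800141	-0.377174	-0.549541	-0.58729	-0.373386	0.414788	0.470086	-0.348894	-0.070609	0.262266	0.996204	0.250183	-0.27516	-0.01701	0.120354	0.760639	0.761211	0.763515
N	-0.780177	0.215556	-0.160178	-1.00771	-0.238311	-0.785154	-0.680311	0.078925	0.595122	0.33603	-0.052446	0.103914	0.552807	0.735471	0.057742	-0.195831	-0.036705	-0.745286	-0.92967	-0.084579	-1.018019
P	0.120027	0.111674	-0.677927	-0.371614	-0.653226	-0.814693	-0.360942	-0.978629	0.765143	0.11411	-0.951357	0.065114	0.771253	0.892192	0.182157	-0.19945	-0.132222	-0.197354	-0.084515	-1.099528	-0.424175
Q	-0.850192	0.215556	0.292852	-1.00771	-0.158611	-0.785154	-0.636074	0.078925	0.58099	-0.066158	0.023895	0.195927	0.552807	-0.054979	0.021283	-0.195831	-0.027626	-0.745286	-1.098701	0.253737	-1.018019
R	-2.530573	1.669909	1.231271	-1.342497	3.807808	1.597702	0.416593	1.027318	-3.204324	-3.149498	2.772729	2.07379	-1.964138	-2.406071	-4.048584	1.754488	0.544479	-1.532395	-1.605793	1.268686	-1.611864
S	-0.180041	0.267497	-1.033879	-0.103784	-0.640652	-0.763351	0.087514	-1.132101	0.707497	0.401822	-0.882878	-0.124138	0.788331	0.641777	0.180182	-0.192001	-0.378755	-0.169055	-0.422577	-1.268686	0.084835
T	-0.050011	-0.096091	-0.580849	-0.070305	-0.661538	-0.817507	-0.45088	-1.139126	0.757092	0.232867	-0.899291	0.189037	0.831242	0.526698	0.181673	-0.200407	-0.09631	-0.168621	-0.253546	-0.761211	0.254505
V	1.080245	-0.667444	-0.645568	1.570152	0.151458	-0.438416	-0.392463	1.826563	0.07747	-0.548411	0.932117	0.542439	-0.479977	-1.299085	0.510769	-0.324833	-0.119012	2.013753	1.267731	-0.930369	1.442194
W	0.810183	-1.654327	2.16969	-0.137263	-0.204992	1.552689	2.765538	-1.122374	-0.502425	2.092222	-1.023422	-3.245596	1.105138	-0.059668	0.320529	-2.100353	3.137725	-0.169883	0.92967	1.607002	-0.084835
Y	0.260059	-1.082974	1.425426	-0.271178	-0.616065	0.193636	0.796228	-1.056446	0.488877	0.600314	-0.9794	-1.318084	1.187934	-0.213294	0.186296	-0.733144	0.864344	-0.179666	0.084515	1.437844	-0.254505
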