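SYNTH_CLUSTER_SET_01	planted-cluster genes	g00001	g00002	g00003	g00004	g00005	g00006	g00007	g00008	g00009	g00010	g00011	g00012	g00013	g00014	g00015	g00016	g00017	g00018	g00019	g00020
SYNTH_CLUSTER_SET_02	planted-cluster genes	g00021	g00022	g00023	g00024	g00025	g00026	g00027	g00028	g00029	g00030	g00031	g00032	g00033	g00034	g00035	g00036	g00037	g00038	g00039	g00040
SYNTH_CLUSTER_SET_03	planted-cluster genes	g00041	g00042	g00043	g00044	g00045	g00046	g00047	g00048	g00049	g00050	g00051	g00052	g00053	g00054	g00055	g00056	g00057	g00058	g00059	g00060
SYNTH_CLUSTER_SET_04	planted-cluster genes	g00061	g00062	g00063	g00064	g00065	g00066	g00067	g00068	g00069	g00070	g00071	g00072	g00073	g00074	g00075	g00076	g00077	g00078	g00079	g00080
SYNTH_CLUSTER_SET_05	planted-cluster genes	g00081	g00082	g00083	g00084	g00085	g00086	g00087	g00088	g00089	g00090	g00091	g00092	g00093	g00094	g00095	g00096	g00097	g00098	g00099	g00100
SYNTH_RANDOM_SET_06	random genes	g00365	g01414	g01865	g00960	g00740	g01189	g01925	g00710	g00326	g01776	g00522	g01156	g00832	g01204	g00725
SYNTH_RANDOM_SET_07	random genes	g00655	g01721	g00379	g01168	g01180	g00664	g00256	g01741	g00303	g01435	g01405	g00876	g01616	g00937	g00608
SYNTH_RANDOM_SET_08	random genes	g00445	g01932	g00713	g00655	g00532	g01178	g01463	g00309	g00724	g01228	g01873	g01207	g00249	g00893	g00637
SYNTH_RANDOM_SET_09	random genes	g01700	g01495	g01658	g00732	g01120	g00632	g01320	g00374	g00749	g01669	g01988	g00937	g00909	g00209	g01787
SYNTH_RANDOM_SET_10	random genes	g00801	g01414	g00969	g00446	g01800	g00709	g01537	g01447	g01565	g00455	g01730	g00680	g01006	g00494	g01672
SYNTH_RANDOM_SET_11	random genes	g01510	g00675	g01123	g00342	g01958	g00453	g01999	g00707	g00416	g01540	g01000	g01439	g01050	g01144	g00386
SYNTH_RANDOM_SET_12	random genes	g01903	g01345	g01755	g01668	g01015	g00322	g01205	g01308	g01452	g01194	g01989	g01734	g00729	g00434	g01849
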