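SYN:0001	BP	g00033	m002	m003	m006	m008
SYN:0002	CC	g00016	g00028	m001	m002	m005	m009	m010
SYN:0003	MF	g00005	g00007	g00040	m001	m002	m003	m004	m005	m006	m007	m008	m009	m010
SYN:0004	BP	g00008	g00020	g00022	g00042	m001	m002	m003	m004	m005	m006	m007	m008	m009	m010
SYN:0005	CC	g00006	g00015	m002	m003	m005	m007	m008	m009	m010
SYN:0006	MF	g00005	g00025	m001	m005	m006	m008	m010
SYN:0007	BP	g00040	g00050	m002	m004	m005	m006	m007	m010
SYN:0008	CC	g00003	g00016	g00022	g00031	m001	m002	m003	m004	m005	m006	m007	m008	m009	m010
SYN:0009	MF	g00028	g00036	g00038	m001	m002	m003	m005	m008	m009	m010
SYN:0010	BP	g00022	g00025	g00034	m001	m002	m003	m004	m005	m006	m007	m008	m010
SYN:0011	CC	g00004	g00022	g00046	m002	m003	m005	m006	m008	m009	m010
SYN:0012	MF	g00019	m002	m003	m008	m009	m010
SYN:0013	BP	g00019	g00027	m001	m004	m005	m006	m008
SYN:0014	CC	g00006	g00007	g00021	g00042	m001	m002	m003	m004	m005	m006	m007	m008	m009	m010
SYN:0015	MF	g00047	m002	m004	m007	m010
SYN:0016	BP	g00011	g00019	g00037	g00041	m001	m002	m003	m004	m005	m006	m007	m008	m009	m010
SYN:0017	CC	g00004	g00014	g00020	g00026	g00027	g00028	g00030	g00032	g00036	g00042	g00043	g00047	m002	m003	m004	m009	m010
SYN:0018	MF	g00001	g00004	g00005	g00006	g00007	g00008	g00009	g00010	g00011	g00012	g00017	g00018	g00020	g00022	g00026	g00028	g00032	g00033	g00034	g00035	g00036	g00038	g00042	g00044	g00046	g00048	g00050	m002	m003	m005	m007	m010
SYN:0019	BP	g00010	g00016	g00020	g00021	g00023	g00026	g00027	g00028	g00040	g00041	g00048	g00049	m005	m006	m009	m010
SYN:0020	CC	g00001	g00003	g00004	g00010	g00014	g00017	g00021	g00022	g00023	g00024	g00027	g00033	g00039	g00041	g00047	g00048	m006	m007	m010
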