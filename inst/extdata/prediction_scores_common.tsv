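gene_id	pooled	microcosm	pictar	mirnaorg	targetscan
Blimp-1	49.9482	15.8908	3.4973	14.1685	16.3916
Bx	58.9239	12.5711	10.0509	21.5938	14.7081
CadN	148.5861	20.0306	46.4332	38.4779	43.6443
CG10737	71.3749	35.504	5.7567	13.7227	16.3916
CG11206	95.6901	9.0084	8.5247	34.9136	43.2434
CG12918	52.1314	20.8109	3.3907	18.0949	9.835
CG13606	52.6384	14.5549	4.7616	16.6199	16.702
CG3077	91.2297	23.2887	6.4559	41.8153	19.6699
CG32105	43.3198	10.3112	2.2363	20.9373	9.835
CG33090	82.8792	21.1135	4.0624	16.7976	40.9057
CG3376	42.0182	8.3405	5.9978	17.845	9.835
CG3534	48.6526	17.7977	3.4824	17.5376	9.835
CG3624	55.4638	16.9653	2.6852	23.3858	12.4274
CG4360	47.9093	18.0506	2.4584	11.0087	16.3916
CG4984	59.4745	18.049	7.6279	7.6745	26.123
CG5599	40.5821	8.8509	1.0127	12.8686	17.8498
CG6129	41.6798	6.8082	2.8427	14.9821	17.0467
CG7510	49.279	14.8554	2.4046	12.5453	19.4736
CG8121	54.1836	7.73	2.9878	8.4767	34.9891
CG8128	94.288	19.9651	3.0917	54.8397	16.3916
CG8303	49.7826	15.8126	3.3083	14.2702	16.3916
CG8323	64.1433	18.4807	4.3704	13.6601	27.6321
CG8360	56.7583	16.8753	5.7226	11.2122	22.9482
CG8417	52.5854	15.8653	4.3959	15.9326	16.3916
CG9376	15.882	7.2495	0.5563	3.189	4.8872
CG9650	62.1572	7.6917	7.0478	23.3065	24.1113
Cpr	47.5051	14.3186	9.1431	14.2084	9.835
Dysb	65.1018	19.433	4.5585	20.0348	21.0755
endoB	24.5428	0.1061	6.1164	7.408	10.9122
Ero1L	45.3898	14.8674	5.0706	15.6169	9.835
garz	31.366	4.712	0.5962	6.4735	19.5843
Gfat2	41.9788	15.844	3.1358	13.1641	9.835
Myd88	6.4706	4.1638	0.0121	2.0501	0.2446
Nak	103.4518	19.0669	16.3947	36.5532	31.437
pdm2	25.7957	6.5096	0.9607	4.8823	13.4431
porin	89.8516	62.5375	2.5203	2.9915	21.8023
Ptp69D	52.3718	14.288	6.8889	19.0121	12.1828
RASSF8	34.0327	4.4412	0.7073	8.3362	20.548
raw	43.2677	11.3523	5.832	15.1805	10.9028
regucalcin	56.0884	15.5743	15.7528	14.9263	9.835
RhoGAP68F	61.4035	14.2428	1.8217	19.0121	26.3269
Sbf	73.9455	28.9451	4.3431	17.0058	23.6515
sens	49.4627	14.7634	2.6482	8.9293	23.1217
Sirt2	44.534	15.6316	5.3448	13.7227	9.835
SP555	61.754	20.8951	7.8086	17.9622	15.088
T48	49.6111	4.379	1.1091	10.2365	33.8865
Thd1	66.7116	19.9882	2.1996	24.2192	20.3047
Tm1	37.4083	9.7281	3.4708	9.6231	14.5862
toe	47.8611	17.745	3.2504	17.0308	9.835
up	94.0563	32.8545	24.6085	24.4104	12.1828
Vha68-1	64.4111	9.5403	3.4957	26.8446	24.5305
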