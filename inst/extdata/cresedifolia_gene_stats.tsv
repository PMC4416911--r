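gene	n	L	zz	H	n_introns	L_eff	S	pi	theta_w	tajima_d	div	mk_p	dos
AT1G07890	114	1125	0.081	0.797	5	455	7	0.00465	0.00290	1.386	0.289	1.0000	-0.083
AT1G61520	120	510	-0.059	0.836	2	164	6	0.00701	0.00796	-0.274	0.190	1.0000	-0.015
AT1G63440	116	1229	0.018	0.903	3	262	9	0.00861	0.00645	0.818	0.201	1.0000	0.015
AT1G69070	104	1748	0.018	0.907	5	492	8	0.00150	0.00305	-1.208	0.138	0.4745	-0.100
AT1G77490	110	1607	0.018	0.793	8	738	7	0.00115	0.00180	-0.838	0.266	0.2018	-0.255
AT2G15970	120	600	0.195	0.424	2	128	1	0.00063	0.00146	-0.629	0.293	0.1807	-0.286
AT2G16500	112	1020	0.033	0.764	0	NA	NA	NA	NA	NA	NA	0.0512	-0.335
AT2G22590	118	831	0.033	0.491	0	NA	NA	NA	NA	NA	NA	0.6995	-0.127
AT2G31610	118	1000	0.057	0.333	3	319	3	0.00094	0.00176	-0.814	0.510	0.1622	-0.625
AT2G36530	120	1224	0.231	0.668	6	424	4	0.00150	0.00176	-0.286	0.265	0.7255	0.102
AT2G42540	120	567	0.231	0.233	1	215	2	0.00217	0.00174	0.371	0.461	1.0000	NA
AT2G44060	120	504	0.231	0.049	0	NA	NA	NA	NA	NA	NA	0.2500	-0.771
AT4G23850	120	856	-0.162	0.627	3	275	2	0.00170	0.00136	0.374	0.159	0.3858	-0.190
AT4G29350	112	950	-0.162	0.913	2	502	12	0.00334	0.00489	-0.843	0.247	0.3275	-0.279
AT5G01950	120	1052	0.037	0.790	3	246	7	0.00396	0.00531	-0.577	0.232	0.2901	0.354
AT5G11490	120	586	-0.082	0.188	2	196	2	0.00034	0.00190	-1.223	0.253	1.0000	-0.200
AT5G14420	120	822	0.167	0.458	4	320	1	0.00132	0.00058	1.406	0.216	0.4953	-0.459
AT5G50100	114	802	0.168	0.460	4	320	2	0.00032	0.00118	-1.089	0.323	0.1110	-0.692
AT5G51750	114	663	0.039	0.574	0	NA	NA	NA	NA	NA	NA	0.0385	-0.272
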