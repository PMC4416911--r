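gene	n	L	zz	H	n_introns	L_eff	S	pi	theta_w	tajima_d	div	mk_p	dos
AT1G07890	116	1125	0.000	0.051	5	426	2	0.00008	0.00088	-1.358	0.299	0.4490	-0.563
AT1G61520	120	510	0.000	0.033	2	166	0	0.00000	0.00000	NA	0.199	0.2143	-0.579
AT1G63440	120	1229	-0.015	0.583	3	263	3	0.00263	0.00213	0.408	0.223	0.4539	-0.140
AT1G69070	110	1748	-0.015	0.688	5	451	5	0.00319	0.00207	1.124	0.149	0.5537	-0.125
AT1G77490	116	1607	-0.015	0.625	8	633	6	0.00065	0.00178	-1.390	0.206	0.1729	-0.422
AT2G15970	120	600	-0.057	0.470	2	146	4	0.00954	0.00511	1.667	0.299	0.0398	-0.694
AT2G16500	120	1020	0.028	0.612	0	NA	NA	NA	NA	NA	NA	1.0000	0.039
AT2G22590	112	831	0.028	0.610	0	NA	NA	NA	NA	NA	NA	0.6825	-0.104
AT2G31610	120	1000	0.163	0.849	3	314	10	0.01073	0.00594	2.009	0.536	0.6918	-0.141
AT2G36530	114	1224	0.174	0.674	6	425	8	0.00477	0.00398	0.487	0.271	0.3029	0.333
AT2G42540	118	567	0.174	0.620	1	278	7	0.00581	0.00471	0.534	0.475	1.0000	0.038
AT2G44060	118	504	-0.004	0.350	0	NA	NA	NA	NA	NA	NA	0.0907	-0.395
AT4G23850	120	856	0.000	0.171	3	268	3	0.00065	0.00209	-1.200	0.171	1.0000	NA
AT4G29350	116	950	0.000	0.181	2	458	12	0.00056	0.00492	-2.305	0.225	1.0000	0.013
AT5G01950	120	1052	0.000	0.017	3	244	0	0.00000	0.00000	NA	0.228	0.3654	-0.647
AT5G11490	120	586	0.000	0.142	2	157	4	0.00320	0.00475	-0.629	0.255	0.5055	0.300
AT5G14420	120	822	-0.066	0.373	4	299	3	0.00105	0.00187	-0.764	0.215	1.0000	0.151
AT5G50100	120	802	0.156	0.718	4	289	10	0.01621	0.00645	3.763	0.291	1.0000	-0.021
AT5G51750	114	663	0.008	0.616	0	NA	NA	NA	NA	NA	NA	0.0284	-0.272
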