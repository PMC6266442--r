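orf_id	type	strand	start	end	size_aa	mw_kda	pi	sd_context	start_codon	predicted_function	hit_identical	hit_smallest_len	hit_pct_identity	aligned_size_aa
ORF1	CDS	+	673	2613	646	72.7	6.09	TGGAGACttacaa	ATG	RNA polymerase	598	646	93	648
ORF2	CDS	+	2640	2846	68	7.89	4.51	AGGATGGcattag	TTG		48	55	87	55
ORF3	CDS	+	3959	4177	72	4.14	8.15	AGGAGAAtaaa	ATG		23	73	32	71
ORF4	CDS	+	4217	4453	78	8.9	9.63	CGGAGAGcagaa	ATG		49	76	64	76
ORF5	CDS	+	4456	4644	62	7.5	4.53	ACGAGGTtaatc	ATG		61	62	98	62
ORF6	CDS	+	4641	4835	64	7.3	9.7	TGGAGGCcaa	ATG		NA	NA	NA	NA
ORF7	CDS	+	4832	5077	81	9.4	4.32	AGGCGGGttggtt	GTG		NA	NA	NA	NA
ORF8	CDS	+	5087	5260	57	6.7	9.25	AGGAGTAttaa	ATG		56	57	98	57
ORF9	CDS	+	5356	5667	103	11.6	4.5	AGGTAATtaa	ATG		84	99	85	99
ORF10	CDS	+	5683	5943	86	9.7	5.6	GGGAGTTatt	ATG		79	86	92	87
ORF11	CDS	+	5936	6118	60	6.4	4.64	TGGGAGTtctgtacc	ATG		NA	NA	NA	NA
ORF12	CDS	+	6121	6348	75	8.4	5.24	AGGATAAtc	ATG		67	75	89	75
ORF13	CDS	+	6345	6575	76	8.6	9.58	ACAAGGTttattgca	ATG		42	68	62	68
ORF14	CDS	+	6639	6929	96	10.7	9.47	TGGAGCAttt	ATG		87	96	91	96
ORF15	CDS	+	6922	7155	77	8.8	5.22	AGAAGGTgaagc	GTG		68	77	88	77
ORF16	CDS	+	7152	7439	95	10.8	9.3	TGGAGAAattaaagca	ATG		84	95	88	95
ORF17	CDS	+	7439	7636	65	7.82	9.81	AGGTGATgta	ATG		29	65	45	68
ORF18	CDS	+	7715	8197	160	18.8	8.79	TGGAGGGctt	ATG		72	160	45	161
ORF19	CDS	+	8323	8700	125	14.2	5.78	AAGAGAAtcttaatc	ATG	ssDNA-binding protein	96	125	77	126
ORF20	CDS	+	8823	9719	298	33.2	7.74	GTGAGGAatatc	ATG		159	229	69	229
ORF21	CDS	+	9775	10125	116	13.1	6.07	CGGAGCAttt	ATG		114	116	98	116
ORF22	CDS	+	10122	10355	77	8.72	5.29	AGGAAGTtaa	ATG		56	77	73	77
ORF23	CDS	+	10345	10614	89	10.3	4.7	AGGAAATccattcc	GTG		NA	NA	NA	NA
ORF24	CDS	+	10607	11023	138	15.7	9.48	AGGAGCTgaaaa	ATG	endolysin	110	131	84	131
ORF25	CDS	+	11044	11322	92	10.9	5.7	TGGAGCAtccg	ATG		NA	NA	NA	NA
ORF26	CDS	+	11309	11857	182	21.2	4.03	GGGAGAAactca	ATG	antirestriction protein	145	181	80	181
ORF27	CDS	+	11850	12089	79	9.2	6.9	CGAAGGGatactattctcaa	ATG		73	79	92	79
ORF28	CDS	+	13092	13295	67	7.5	4.58	TGGAGAGttcct	ATG		57	67	85	69
ORF29	CDS	+	13292	13582	96	11.3	9.1	AGGAGCTgcaaaa	ATG		NA	NA	NA	NA
ORF30	CDS	+	13579	13869	96	10.6	5.25	CGGAGTTccatt	TTG		93	96	97	97
ORF31	CDS	+	13872	14546	224	25.9	8.28	ACAAGGCcactaaaa	ATG		223	224	99	224
ORF32	CDS	+	14670	15008	112	12.3	4.47	ATAAGGTatatacaa	ATG		111	112	99	112
ORF33	CDS	+	15395	15532	45	5.1	8.99	CGGAGCAataattaat	TTG		NA	NA	NA	NA
ORF34	CDS	+	15547	15789	80	8.8	9.24	AGAAGCTatgccaat	GTG		77	80	96	80
tRNA-Arg	tRNA	+	15909	16003	NA	NA	NA	NA	NA	tRNA-Arg	NA	NA	99	NA
ORF35	CDS	+	16029	16169	46	4.8	3.76	TGGAGTCctc	ATG		NA	NA	NA	NA
ORF36	CDS	+	16178	16414	78	8.5	9.05	AGGTGATtt	ATG		77	78	99	78
ORF37	CDS	+	17404	17634	76	8.5	4.89	TGGAGAGaaac	ATG		74	76	97	76
ORF38	CDS	+	17691	18341	216	24.8	5.99	CGGAGAGcaa	ATG	thymidylate synthase	196	216	91	216
ORF39	CDS	+	18346	20109	587	66	5.95	ACCAGGAataaataa	ATG	helicase/primase	560	587	95	587
ORF40	CDS	+	20175	22109	644	74.6	6.41	TGGAGCCatact	GTG	DNA polymerase	637	644	99	644
ORF41	CDS	+	22109	22381	90	10.1	4.37	CAGAGATtcacta	ATG		86	90	96	90
ORF42	CDS	+	22412	23278	288	31	4.86	AGGTACTcaaa	ATG		288	288	100	288
ORF43	CDS	+	23312	24349	345	39.4	8.09	GGGAGCCtttaatt	TTG	exonuclease	342	345	99	345
ORF44	CDS	+	24361	24885	174	20.1	9.46	TGGAGTTgga	ATG		173	174	99	174
ORF45	CDS	+	24875	25630	251	28.5	8.64	AGAAAGAatctta	ATG	DNA ligase	233	251	93	251
ORF46	CDS	+	25623	26249	208	23.5	6.38	GTGAGGAaagtt	TTG		203	208	98	208
ORF47	CDS	+	26252	26839	195	20.7	6.66	ATCAAGTagagaaataatc	ATG	deoxyuridine 5'-triphosphate nucleotidylhydrolase	164	195	82	199
ORF48	CDS	+	26858	27064	68	8.2	4.32	TGGAGCAtcc	ATG		37	68	54	73
ORF49	CDS	+	27082	27411	109	12.2	9.7	TGGAACCtatctgaa	ATG		109	109	100	109
ORF50	CDS	+	27467	27652	61	7	4.4	CGGAGTCgctt	ATG		61	61	100	61
ORF51	CDS	+	27672	29690	672	76	6.02	AAGAGAAcgaatca	ATG	large subunit terminase	667	671	99	671
ORF52	CDS	+	29693	29905	70	7.9	9.18	TGGATGTaaat	ATG		70	70	100	70
ORF53	CDS	+	29905	31221	438	49.1	8.16	AGGAAGAaata	ATG	portal protein	434	438	99	438
ORF54	CDS	+	31190	32254	354	39	4.8	AAAGGGTaacgcaa	GTG		353	354	99	354
ORF55	CDS	+	32264	32737	157	16.4	6.26	ATAAGGTaagaca	ATG		147	157	94	157
ORF56	CDS	+	32818	33030	70	7.3	6.06	TGTAACT	GTG		51	70	73	90
ORF57	CDS	+	33086	34093	335	36.7	5.17	TGGATTAaattac	ATG	major capsid protein	323	335	96	335
ORF58	CDS	+	34140	34580	146	16.1	5.34	AAGAGAAatagta	ATG		116	146	79	146
ORF59	CDS	+	34581	34970	129	14.6	4.48	AGTTGGCgtaa	ATG		124	129	96	129
ORF60	CDS	+	34967	35329	120	13.9	9.16	GGGTCACagtt	TTG		120	120	100	120
ORF61	CDS	+	35326	35838	170	19.3	4.98	AGGAGTTagagaa	ATG		167	170	98	170
ORF62	CDS	+	35839	37287	482	50.9	4.75	AGGGAATctaa	ATG		447	482	93	482
ORF63	CDS	+	37298	37753	151	16.5	6.55	AGGTGCGataa	GTG		148	151	98	151
ORF64	CDS	+	37765	38223	152	17.3	5.1	AGTAAGT	ATG		152	152	100	152
ORF65	CDS	+	38229	38399	56	6.7	4.67	CGGAGACagtttagtatcc	ATG		55	56	98	73
ORF66	CDS	+	38383	42108	1241	134.6	5.36	AGAAACTcgaaccagtag	ATG	tail fiber	946	1239	76	1239
ORF67	CDS	+	42182	43291	369	40.7	5.13	AATAGGTatatcgca	ATG		366	369	99	369
ORF68	CDS	+	43291	44178	295	31.2	5.98	TGGAGTCatttta	ATG		295	295	100	295
ORF69	CDS	+	44175	44537	120	13.7	5.07	GGGACGTatcct	ATG		120	120	100	120
ORF70	CDS	+	44530	45324	264	28.2	5.8	AGAGTGTacttgaac	GTG	baseplate assembly protein	263	264	99	264
ORF71	CDS	+	45324	45695	123	13.5	5.22	ATGAAATa	ATG		117	123	95	123
ORF72	CDS	+	45671	46828	385	41.2	4.55	CGGAATTcttaac	ATG		361	385	94	385
ORF73	CDS	+	46830	47471	213	23.5	5.82	CAGATGTgacagtataat	ATG		193	213	91	213
ORF74	CDS	+	47471	48619	382	42.3	5.49	CGGAGAAata	ATG		342	382	90	382
ORF75	CDS	+	48619	50016	465	50.2	8.17	AGGCCATa	ATG		314	465	68	465
ORF76	CDS	+	50025	51071	348	36.3	6.6	AGGATTCaaa	ATG	tail fiber protein	250	348	72	356
ORF77	CDS	+	51079	51420	113	12.3	7.95	AGGAACTc	ATG	holin	110	113	97	113
ORF78	CDS	+	51438	51992	184	20.7	9.57	AGGAACTcga	ATG	endolysin	178	184	97	184
ORF79	CDS	+	51992	53092	366	42.2	4.76	AGGAAATctgta	ATG	ribonucleotide reductase beta subunit	340	366	93	372
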