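strain	plasmid	size_kb	cds	nap_count	families	protein_ids	accession
A. ferrivorans PQ33	pAfPQ33_1	10.2	10	1	KfrA	ARU59618.1	CP021414.1
A. ferrivorans CF27	AFERRIp	46.4	50	1	KfrA	SMH67819.1	LT841306.1
F. caldus ATCC 51756	pACA1.1	27.5	33	2	KfrA;IHF_A	AIA56783.1;AIA56791.1	CP005988.1
F. caldus MTH-04	p1	190.8	229	4	HU;HU;IHF_A;HU	AUW34137.1;AUW34251.1;AUW34139.1;AUW34211.1	CP026329.1
F. caldus MTH-04	p2	32.8	66	2	IHF_A;KfrA	AUW34268.1;AUW34286.1	CP026330.1
F. caldus SM-1	mega plasmid	251.8	255	2	HU;IHF_A	AEK59566.1;AEK59568.1	CP002574.1
F. caldus SM-1	pLAtc3	29.7	28	1	IHF_A	AEK59821.1	CP002577.1
F. caldus SM-1	pLAtc2	14.1	14	1	IHF_A	AEK59799.1	CP002576.1
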