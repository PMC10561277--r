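lineage	family	total	dose_min	dose_max
AFE	EbfC	14	1	1
AFE	Fis	13	1	1
AFE	H-NS	0	0	0
AFE	HU	43	2	5
AFE	IHF_A	58	2	6
AFE	IHF_B	22	1	3
AFE	Lrp	14	1	1
AFE	SMC	15	1	2
AFE	Alba_2	11	1	1
AFE	KfrA	5	1	2
AFE	NdpA	0	0	0
AFE	MukB	0	0	0
AFG	EbfC	1	1	1
AFG	Fis	1	1	1
AFG	H-NS	0	0	0
AFG	HU	3	3	3
AFG	IHF_A	2	2	2
AFG	IHF_B	1	1	1
AFG	Lrp	1	1	1
AFG	SMC	1	1	1
AFG	Alba_2	0	0	0
AFG	KfrA	2	2	2
AFG	NdpA	0	0	0
AFG	MukB	0	0	0
AFD	EbfC	9	1	1
AFD	Fis	9	1	1
AFD	H-NS	1	1	1
AFD	HU	43	3	6
AFD	IHF_A	31	2	5
AFD	IHF_B	14	1	2
AFD	Lrp	9	1	1
AFD	SMC	9	1	1
AFD	Alba_2	2	1	1
AFD	KfrA	7	1	2
AFD	NdpA	0	0	0
AFD	MukB	0	0	0
AFP	EbfC	9	1	1
AFP	Fis	9	1	1
AFP	H-NS	1	1	1
AFP	HU	18	1	3
AFP	IHF_A	18	1	3
AFP	IHF_B	11	1	2
AFP	Lrp	8	1	1
AFP	SMC	10	1	2
AFP	Alba_2	0	0	0
AFP	KfrA	2	1	1
AFP	NdpA	0	0	0
AFP	MukB	0	0	0
AFV	EbfC	7	1	1
AFV	Fis	7	1	1
AFV	H-NS	6	1	1
AFV	HU	18	1	4
AFV	IHF_A	35	3	9
AFV	IHF_B	20	1	7
AFV	Lrp	9	1	2
AFV	SMC	7	1	1
AFV	Alba_2	1	1	1
AFV	KfrA	5	1	2
AFV	NdpA	0	0	0
AFV	MukB	0	0	0
AFN	EbfC	1	1	1
AFN	Fis	1	1	1
AFN	H-NS	0	0	0
AFN	HU	1	1	1
AFN	IHF_A	1	1	1
AFN	IHF_B	1	1	1
AFN	Lrp	2	2	2
AFN	SMC	1	1	1
AFN	Alba_2	0	0	0
AFN	KfrA	0	0	0
AFN	NdpA	0	0	0
AFN	MukB	0	0	0
ATH	EbfC	20	1	1
ATH	Fis	20	1	1
ATH	H-NS	36	1	3
ATH	HU	91	1	7
ATH	IHF_A	77	2	5
ATH	IHF_B	62	2	6
ATH	Lrp	21	1	1
ATH	SMC	21	1	1
ATH	Alba_2	0	0	0
ATH	KfrA	1	1	1
ATH	NdpA	0	0	0
ATH	MukB	3	1	1
ACO	EbfC	1	1	1
ACO	Fis	1	1	1
ACO	H-NS	1	1	1
ACO	HU	4	4	4
ACO	IHF_A	3	3	3
ACO	IHF_B	2	2	2
ACO	Lrp	1	1	1
ACO	SMC	1	1	1
ACO	Alba_2	0	0	0
ACO	KfrA	0	0	0
ACO	NdpA	0	0	0
ACO	MukB	0	0	0
ASU	EbfC	1	1	1
ASU	Fis	1	1	1
ASU	H-NS	0	0	0
ASU	HU	5	5	5
ASU	IHF_A	2	2	2
ASU	IHF_B	5	5	5
ASU	Lrp	1	1	1
ASU	SMC	1	1	1
ASU	Alba_2	0	0	0
ASU	KfrA	0	0	0
ASU	NdpA	1	1	1
ASU	MukB	0	0	0
AMA	EbfC	1	1	1
AMA	Fis	1	1	1
AMA	H-NS	0	0	0
AMA	HU	2	2	2
AMA	IHF_A	1	1	1
AMA	IHF_B	1	1	1
AMA	Lrp	1	1	1
AMA	SMC	1	1	1
AMA	Alba_2	1	1	1
AMA	KfrA	0	0	0
AMA	NdpA	0	0	0
AMA	MukB	0	0	0
AMO	EbfC	1	1	1
AMO	Fis	1	1	1
AMO	H-NS	0	0	0
AMO	HU	1	1	1
AMO	IHF_A	1	1	1
AMO	IHF_B	3	3	3
AMO	Lrp	1	1	1
AMO	SMC	1	1	1
AMO	Alba_2	0	0	0
AMO	KfrA	1	1	1
AMO	NdpA	0	0	0
AMO	MukB	0	0	0
FCA	EbfC	18	1	1
FCA	Fis	18	1	1
FCA	H-NS	0	0	0
FCA	HU	42	1	5
FCA	IHF_A	55	1	5
FCA	IHF_B	21	1	2
FCA	Lrp	0	0	0
FCA	SMC	18	1	2
FCA	Alba_2	0	0	0
FCA	KfrA	17	1	2
FCA	NdpA	0	0	0
FCA	MukB	0	0	0
ICO	EbfC	6	1	1
ICO	Fis	6	1	1
ICO	H-NS	0	0	0
ICO	HU	6	1	1
ICO	IHF_A	6	1	1
ICO	IHF_B	6	1	1
ICO	Lrp	0	0	0
ICO	SMC	6	1	1
ICO	Alba_2	0	0	0
ICO	KfrA	2	1	1
ICO	NdpA	0	0	0
ICO	MukB	0	0	0
IYE	EbfC	1	1	1
IYE	Fis	1	1	1
IYE	H-NS	0	0	0
IYE	HU	1	1	1
IYE	IHF_A	1	1	1
IYE	IHF_B	0	0	0
IYE	Lrp	0	0	0
IYE	SMC	1	1	1
IYE	Alba_2	0	0	0
IYE	KfrA	0	0	0
IYE	NdpA	0	0	0
IYE	MukB	0	0	0
AMS	EbfC	1	1	1
AMS	Fis	1	1	1
AMS	H-NS	0	0	0
AMS	HU	1	1	1
AMS	IHF_A	1	1	1
AMS	IHF_B	1	1	1
AMS	Lrp	1	1	1
AMS	SMC	1	1	1
AMS	Alba_2	0	0	0
AMS	KfrA	0	0	0
AMS	NdpA	0	0	0
AMS	MukB	0	0	0
TTP	EbfC	1	1	1
TTP	Fis	1	1	1
TTP	H-NS	0	0	0
TTP	HU	1	1	1
TTP	IHF_A	1	1	1
TTP	IHF_B	1	1	1
TTP	Lrp	0	0	0
TTP	SMC	1	1	1
TTP	Alba_2	0	0	0
TTP	KfrA	0	0	0
TTP	NdpA	0	0	0
TTP	MukB	0	0	0
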