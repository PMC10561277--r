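lineage	species	n_genomes	total_naps	naps_median	naps_min	naps_max
AFE	Acidithiobacillus ferrooxidans	14	195	15	10	17
AFG	Acidithiobacillus ferruginosus	1	12	12	12	12
AFD	Acidithiobacillus ferridurans	9	134	15	11	17
AFP	Acidithiobacillus ferriphilus	9	86	10	6	12
AFV	Acidithiobacillus ferrivorans	7	115	16	13	25
AFN	Acidithiobacillus ferrianus	1	8	8	8	8
ATH	Acidithiobacillus thiooxidans	21	352	17	11	23
ACO	Acidithiobacillus concretivorus	1	14	14	14	14
ASU	Acidithiobacillus sulfurivorans	1	17	17	17	17
AMA	Acidithiobacillus marinus	1	9	9	9	9
AMO	Acidithiobacillus monserratensis	1	10	10	10	10
FCA	Fervidacidithiobacillus caldus	18	189	10	7	14
ICO	Igneacidithiobacillus copahuensis	6	38	6	6	7
IYE	Igneacidithiobacillus yellowstonensis	1	5	5	5	5
AMS	Ambacidithiobacillus sulfuriphilus	1	7	7	7	7
TTP	Thermithiobacillus tepidarius	1	6	6	6	6
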