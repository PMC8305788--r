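drug	cell_line	ic50_uM
Gefitinib	MCF-7	35.19
Gefitinib	MDA-MB-231	55.20
Gefitinib	SK-BR-3	5.55
Irinotecan	MCF-7	34.76
Irinotecan	MDA-MB-231	201.27
Irinotecan	SK-BR-3	26.36
Exemestane	MCF-7	145.78
Exemestane	MDA-MB-231	127.37
Exemestane	SK-BR-3	128.38
Idarubicin	MCF-7	0.31
Idarubicin	MDA-MB-231	0.26
Idarubicin	SK-BR-3	0.02
Cisplatin	MCF-7	47.12
Cisplatin	MDA-MB-231	47.12
Cisplatin	SK-BR-3	8.46
Topotecan	MCF-7	0.48
Topotecan	MDA-MB-231	103.57
Topotecan	SK-BR-3	0.74
Sunitinib	MCF-7	4.05
Sunitinib	MDA-MB-231	8.37
Sunitinib	SK-BR-3	5.94
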