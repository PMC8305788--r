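combination_id	drugs	predicted_subtypes	trial_subtypes	effectiveness
DC000083	arzoxifene + LG100268	TNBC/HER2+	TNBC/HER2+	efficacious
DC000132	paclitaxel + trastuzumab	HER2+/LuminalB	HER2+/LuminalB	efficacious
DC000225	gemcitabine + trastuzumab	HER2+	HER2+/LuminalB	efficacious
DC000227	epirubicin + trastuzumab	HER2+	HER2+/LuminalB	efficacious
DC000231	trastuzumab + vinorelbine	HER2+	HER2+/LuminalB	efficacious
DC000233	cyclophosphamide + trastuzumab	HER2+/LuminalB	HER2+/LuminalB	efficacious
DC000236	carboplatin + trastuzumab	HER2+	HER2+/LuminalB	efficacious
DC000649	lapatinib + paclitaxel	HER2+/LuminalB	HER2+/LuminalB	efficacious
DC006857	cediranib + olaparib	TNBC	TNBC/HER2+	efficacious
DC001856	anastrozole + gefitinib	TNBC/HER2+	LuminalA/LuminalB	non-efficacious
DC002772	fulvestrant + gefitinib	TNBC/HER2+	LuminalA/LuminalB	non-efficacious
DC000089	gefitinib + trastuzumab	HER2+	HER2+	non-efficacious
DC000220	lapatinib + letrozole	TNBC/HER2+	LuminalA/LuminalB	efficacious
DC000229	doxorubicin + trastuzumab	LuminalA	HER2+	efficacious
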