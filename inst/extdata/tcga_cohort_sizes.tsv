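cancer_type	description	n_normal	n_cancer
BLCA	Bladder urothelial carcinoma	19	414
BRCA	Breast invasive carcinoma	113	1102
COAD	Colon adenocarcinoma	41	471
ESCA	Esophageal carcinoma	11	159
HNSC	Head and neck squamous cell carcinoma	13	127
KIRC	Kidney renal clear cell carcinoma	72	538
LIHC	Liver hepatocellular carcinoma	50	371
LUAD	Lung adenocarcinoma	59	533
PRAD	Prostate adenocarcinoma	52	498
STAD	Stomach adenocarcinoma	32	375
THCA	Thyroid carcinoma	58	502
UCEC	Uterine corpus endometrial carcinoma	23	551
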