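case_id	n_noncoding_t1	n_noncoding_t2	n_shared_noncoding	status_11p15	germline_genes
SJWLM066770	136	119	0	LOH	REST
SJWLM066771	54	74	6	LOI	No
SJWLM066773	38	41	0	ROI	TRIM28,BRCA1
SJWLM066776	122	174	5	LOH	WT1
SJWLM066777	69	59	0	ROI	TRIM28
SJWLM066778	379	68	1	LOI	No
SJWLM066779	83	230	0	LOI	BLM
SJWLM066780	97	104	0	LOH	WT1
SJWLM066784	73	83	1	LOI	No
SJWLM066789	125	58	2	LOH	DICER1
SJWLM066792	79	16	1	LOI	ASXL1,NYNRIN
SJWLM069391	102	121	63	LOI	No
SJWLM069394	43	104	1	LOI/ROI	No
SJWLM069396	38	90	2	LOH	WT1
SJWLM069399	136	55	1	LOI	No
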