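locus_id	gene	repeat_unit	normal_max	pathologic_min	inheritance
HTT_CAG	HTT	CAG	35	40	AD
ATXN3_CAG	ATXN3	CAG	44	60	AD
RFC1_AAGGG	RFC1	AAGGG	11	400	AR
FXN_GAA	FXN	GAA	33	66	AR
FMR1_CGG	FMR1	CGG	54	200	XR
DMPK_CTG	DMPK	CTG	34	50	AD
C9ORF72_GGGGCC	C9ORF72	GGGGCC	24	31	AD
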