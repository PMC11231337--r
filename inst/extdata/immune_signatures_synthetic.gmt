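CTL	synthetic placeholder immune signature; not the published gene list	CD8A	CD8B	GZMA	GZMB	GZMK	PRF1	IFNG	NKG7	GNLY	KLRK1	KLRD1	EOMES	TBX21	CST7	CCL5	FASLG	ZAP70	CD3E	LAG3	IDO1
TREG	synthetic placeholder immune signature; not the published gene list	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF4	TNFRSF18	CCR4	CCR8	TIGIT	LRRC32	IL10RA	ENTPD1	NT5E	LAYN	BATF	SOCS2	CD27	ICOS	MAGEH1	TBC1D4
M1	synthetic placeholder immune signature; not the published gene list	NOS2	TNF	IL1B	IL6	IL12B	IL23A	CD80	CD86	FCGR1A	SOCS1	IRF5	CXCL11	PTGS2	KYNU	IRF1	CD40	SLAMF7	GBP1	ANKRD22	APOL6
M2	synthetic placeholder immune signature; not the published gene list	CD163	MRC1	MSR1	IL10	CCL22	CCL17	TGFB1	ARG1	STAB1	CD209	LYVE1	FCGR2B	CCL13	CLEC7A	MAF	CHI3L1	F13A1	FOLR2	SLC38A6	CTSC
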