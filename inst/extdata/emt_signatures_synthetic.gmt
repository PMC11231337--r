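TUMOR_EPI	synthetic placeholder gene set reproducing the published arm size; not the published gene list	CDH1	EPCAM	CLDN3	CLDN4	CLDN7	KRT5	KRT8	KRT14	KRT17	KRT18	KRT19	ESRP1	ESRP2	GRHL2	DSP	OCLN	TJP1	TJP3	CRB3	PKP3	DSG2	DSG3	F11R	MARVELD3	CDS1	ST14	SPINT1	SPINT2	RAB25	MYO5B	EHF	ELF3	FOXA1	GATA3	IRF6	JUP	LLGL2	MAP7	PRSS8	TMPRSS2	SYNEPI001	SYNEPI002	SYNEPI003	SYNEPI004	SYNEPI005	SYNEPI006	SYNEPI007	SYNEPI008	SYNEPI009	SYNEPI010	SYNEPI011	SYNEPI012	SYNEPI013	SYNEPI014	SYNEPI015	SYNEPI016	SYNEPI017	SYNEPI018	SYNEPI019	SYNEPI020	SYNEPI021	SYNEPI022	SYNEPI023	SYNEPI024	SYNEPI025	SYNEPI026	SYNEPI027	SYNEPI028	SYNEPI029	SYNEPI030	SYNEPI031	SYNEPI032	SYNEPI033	SYNEPI034	SYNEPI035	SYNEPI036	SYNEPI037	SYNEPI038	SYNEPI039	SYNEPI040	SYNEPI041	SYNEPI042	SYNEPI043	SYNEPI044	SYNEPI045	SYNEPI046	SYNEPI047	SYNEPI048	SYNEPI049	SYNEPI050	SYNEPI051	SYNEPI052	SYNEPI053	SYNEPI054	SYNEPI055	SYNEPI056	SYNEPI057	SYNEPI058	SYNEPI059	SYNEPI060	SYNEPI061	SYNEPI062	SYNEPI063	SYNEPI064	SYNEPI065	SYNEPI066	SYNEPI067	SYNEPI068	SYNEPI069	SYNEPI070	SYNEPI071	SYNEPI072	SYNEPI073	SYNEPI074	SYNEPI075	SYNEPI076	SYNEPI077	SYNEPI078	SYNEPI079	SYNEPI080	SYNEPI081	SYNEPI082	SYNEPI083	SYNEPI084	SYNEPI085	SYNEPI086	SYNEPI087	SYNEPI088	SYNEPI089	SYNEPI090	SYNEPI091	SYNEPI092	SYNEPI093	SYNEPI094	SYNEPI095	SYNEPI096	SYNEPI097	SYNEPI098	SYNEPI099	SYNEPI100	SYNEPI101	SYNEPI102	SYNEPI103	SYNEPI104	SYNEPI105
TUMOR_MES	synthetic placeholder gene set reproducing the published arm size; not the published gene list	VIM	CDH2	FN1	ZEB1	ZEB2	SNAI1	SNAI2	TWIST1	TWIST2	FOXC2	PRRX1	MMP2	MMP3	MMP9	SPARC	COL1A1	COL1A2	COL3A1	COL5A1	COL5A2	COL6A3	FBN1	THBS1	THBS2	POSTN	ACTA2	TAGLN	S100A4	CALD1	TNC	SERPINE1	LOXL2	PDGFRB	FAP	AXL	MSN	EMP3	GEM	WNT5A	DCN	SYNMES001	SYNMES002	SYNMES003	SYNMES004	SYNMES005	SYNMES006	SYNMES007	SYNMES008	SYNMES009	SYNMES010	SYNMES011	SYNMES012	SYNMES013	SYNMES014	SYNMES015	SYNMES016	SYNMES017	SYNMES018	SYNMES019	SYNMES020	SYNMES021	SYNMES022	SYNMES023	SYNMES024	SYNMES025	SYNMES026	SYNMES027	SYNMES028	SYNMES029	SYNMES030	SYNMES031	SYNMES032	SYNMES033	SYNMES034	SYNMES035	SYNMES036	SYNMES037	SYNMES038	SYNMES039	SYNMES040	SYNMES041	SYNMES042	SYNMES043	SYNMES044	SYNMES045	SYNMES046	SYNMES047	SYNMES048	SYNMES049	SYNMES050	SYNMES051	SYNMES052	SYNMES053	SYNMES054	SYNMES055	SYNMES056	SYNMES057	SYNMES058	SYNMES059	SYNMES060	SYNMES061	SYNMES062	SYNMES063	SYNMES064	SYNMES065	SYNMES066	SYNMES067	SYNMES068	SYNMES069	SYNMES070	SYNMES071	SYNMES072	SYNMES073	SYNMES074	SYNMES075	SYNMES076	SYNMES077	SYNMES078	SYNMES079	SYNMES080	SYNMES081	SYNMES082	SYNMES083	SYNMES084	SYNMES085	SYNMES086	SYNMES087	SYNMES088	SYNMES089	SYNMES090	SYNMES091	SYNMES092	SYNMES093	SYNMES094	SYNMES095	SYNMES096	SYNMES097	SYNMES098	SYNMES099	SYNMES100	SYNMES101	SYNMES102	SYNMES103	SYNMES104	SYNMES105	SYNMES106	SYNMES107	SYNMES108	SYNMES109	SYNMES110	SYNMES111	SYNMES112	SYNMES113	SYNMES114	SYNMES115	SYNMES116	SYNMES117	SYNMES118	SYNMES119	SYNMES120	SYNMES121	SYNMES122	SYNMES123	SYNMES124	SYNMES125	SYNMES126	SYNMES127	SYNMES128	SYNMES129	SYNMES130
CELLLINE_EPI	synthetic placeholder gene set reproducing the published arm size; not the published gene list	CDH1	EPCAM	CLDN3	CLDN4	CLDN7	KRT5	KRT8	KRT14	KRT17	KRT18	KRT19	ESRP1	ESRP2	GRHL2	DSP	OCLN	TJP1	TJP3	CRB3	PKP3	DSG2	DSG3	F11R	MARVELD3	CDS1	ST14	SPINT1	SPINT2	RAB25	MYO5B	EHF	ELF3	FOXA1	GATA3	IRF6	JUP	LLGL2	MAP7	PRSS8	TMPRSS2	SYNEPI001	SYNEPI002	SYNEPI003	SYNEPI004	SYNEPI005	SYNEPI006	SYNEPI007	SYNEPI008	SYNEPI009	SYNEPI010	SYNEPI011	SYNEPI012	SYNEPI013	SYNEPI014	SYNEPI015	SYNEPI016	SYNEPI017	SYNEPI018	SYNEPI019	SYNEPI020	SYNEPI021	SYNEPI022	SYNEPI023	SYNEPI024	SYNEPI025	SYNEPI026	SYNEPI027	SYNEPI028	SYNEPI029	SYNEPI030	SYNEPI031	SYNEPI032	SYNEPI033	SYNEPI034	SYNEPI035	SYNEPI036	SYNEPI037	SYNEPI038	SYNEPI039	SYNEPI040	SYNEPI041	SYNEPI042	SYNEPI043	SYNEPI044	SYNEPI045	SYNEPI046	SYNEPI047	SYNEPI048	SYNEPI049	SYNEPI050	SYNEPI051	SYNEPI052	SYNEPI053	SYNEPI054	SYNEPI055	SYNEPI056	SYNEPI057	SYNEPI058	SYNEPI059	SYNEPI060	SYNEPI061	SYNEPI062	SYNEPI063	SYNEPI064	SYNEPI065	SYNEPI066	SYNEPI067	SYNEPI068	SYNEPI069	SYNEPI070	SYNEPI071	SYNEPI072	SYNEPI073	SYNEPI074	SYNEPI075	SYNEPI076	SYNEPI077	SYNEPI078	SYNEPI079	SYNEPI080	SYNEPI081	SYNEPI082	SYNEPI083	SYNEPI084	SYNEPI085	SYNEPI086	SYNEPI087	SYNEPI088	SYNEPI089	SYNEPI090	SYNEPI091	SYNEPI092	SYNEPI093	SYNEPI094	SYNEPI095	SYNEPI096	SYNEPI097	SYNEPI098	SYNEPI099	SYNEPI100	SYNEPI101	SYNEPI102	SYNEPI103	SYNEPI104	SYNEPI105	SYNEPI106	SYNEPI107	SYNEPI108	SYNEPI109	SYNEPI110	SYNEPI111	SYNEPI112	SYNEPI113	SYNEPI114	SYNEPI115	SYNEPI116	SYNEPI117	SYNEPI118	SYNEPI119	SYNEPI120	SYNEPI121	SYNEPI122	SYNEPI123	SYNEPI124	SYNEPI125	SYNEPI126	SYNEPI127	SYNEPI128	SYNEPI129	SYNEPI130
CELLLINE_MES	synthetic placeholder gene set reproducing the published arm size; not the published gene list	VIM	CDH2	FN1	ZEB1	ZEB2	SNAI1	SNAI2	TWIST1	TWIST2	FOXC2	PRRX1	MMP2	MMP3	MMP9	SPARC	COL1A1	COL1A2	COL3A1	COL5A1	COL5A2	COL6A3	FBN1	THBS1	THBS2	POSTN	ACTA2	TAGLN	S100A4	CALD1	TNC	SERPINE1	LOXL2	PDGFRB	FAP	AXL	MSN	EMP3	GEM	WNT5A	DCN	SYNMES001	SYNMES002	SYNMES003	SYNMES004	SYNMES005	SYNMES006	SYNMES007	SYNMES008
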