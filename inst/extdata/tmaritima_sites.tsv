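tf	genome	site_id	operons	dual_with	validated
AraR	Tmar	AraR_ara_div	araEFG;TM0280-abfA-araA		0
AraR	Tmar	AraR_araR	araR-araMDB		0
BglR	Tmar	BglR_bgl	bglREFGKL-TM0026-bglB-lamA		1
CelR	Tmar	CelR_cel	celEFGKLR		0
CelR	Tmar	CelR_cel12	cel12AB		0
CelR	Tmar	CelR_TM0312	TM0312-TM0313		0
CelR	Tmar	CelR_cbpA	cbpA-bglA		0
CelR	Tmar	CelR_celQ	celQ		0
CelR	Tmar	CelR_glo	gloR;gloEFGKL-cel74-fucAI	GloR	0
GloR	Tmar	GloR_glo	gloR;gloEFGKL-cel74-fucAI	CelR	0
ChiR	Tmar	ChiR_chi	chiR-chiEFG-cbsA-nagAB		1
GalR	Tmar	GalR_ltp	ltpEFGKL-lacA-galKT-galR		0
GalR	Tmar	GalR_gan	ganEFG-ganAB-TM1194		0
UxaR	Tmar	UxaR_pelA	pelA		1
UxaR	Tmar	UxaR_agu	aguEFG		1
UxaR	Tmar	UxaR_aldH	aldH-pelB-gnd-uxaRED-gntEK		1
UxaR	Tmar	UxaR_kdgA	kdgAK-uxuBA		1
KdgR	Tmar	KdgR_kdgR	kdgR-uxaC-TM0055		0
KdgR	Tmar	KdgR_xlo	xynB;xloEFGKL-xyl3-axeA	XylR	0
KdgR	Tmar	KdgR_xtp	xynA-cenC;xtpFGKLE-aguA-xghA	XylR	0
XylR	Tmar	XylR_xynB	xynB	KdgR	1
XylR	Tmar	XylR_xlo	xloEFGKL-xyl3-axeA	KdgR	1
XylR	Tmar	XylR_xtp	xynA-cenC;xtpFGKLE-aguA-xghA	KdgR	1
XylR	Tmar	XylR_xylR	xylR-adhB-xylFUEKB		1
XylR	Tmar	XylR_xylA	xylA		1
XylR	Tmar	XylR_xtpN	xtpN-bgaL		1
IolR	Tmar	IolR_iol	iolR-inoEFGK-iolG		1
RbsR	Tmar	RbsR_rbs	rbsR-rbsABC-rbsKD-tktAB-abnAB		0
GluR	Tmar	GluR_glu	gluEFK-gluR		1
GluR	Tmar	GluR_tre	treEFG	TreR	1
TreR	Tmar	TreR_treT	treT-treR		1
TreR	Tmar	TreR_tre	treEFG	GluR	1
ManR	Tmar	ManR_man	manBDCR		1
ManR	Tmar	ManR_mtp	mtpEFGKL-cel5-man5		1
RhaR	Tmar	RhaR_rhaR	rhaR-agu4C		0
RhaR	Tmar	RhaR_rhaM	rhaMADBC		0
RhaR	Tmar	RhaR_rtp	rtpEFGKL-gusB-TM1061		0
UgtR	Tmar	UgtR_ugt	ugtR-ugtEFGK-TM1225-TM1226		0
UctR	Tmar	UctR_uct	uctR-uctMPQ-TM0324-TM0325		0
UgpR	Tmar	UgpR_ugp	ugpR-ugpEFG-TM1853-TM1854-TM1855		0
FruR	Tnap	FruR_fru	fruR-fruAB-fruK-fru1-fru2		0
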