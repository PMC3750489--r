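pathway	abbrev	regulators	transporters	n_enzymes	n_total_genes	n_regulon_genes	in_tmaritima
Central carbohydrate metabolism	CCM			18	18	NA	1
Arabinose, arabinosides	Ara	AraR	AraEFG	6	11	10	1
Beta-glucosides	Bgl	BglR	BglEFGKL	2	9	9	1
Cellobiose	Cel	CelR	CelEFGKL	7	13	13	1
Xyloglucan oligosaccharides	Glo	GloR	GloEFGKL	3	9	9	1
Chitobiose, chitin	Chi	ChiR	ChiEFG	3	7	7	1
Fructose	Fru	FruR	FruAB	2	7	6	0
Galactose, galactosides	Gal	GalR	LtpEFGKL,GanEFG	7	16	15	1
Glycerol	Glp	GlpP	GlpABC,GlpF	2	7	NA	1
Digalacturonate, pectin	Uxa	UxaR	AguEFG	15	19	16	1
Glucuronate	Kdg	KdgR		1	3	3	1
Xylose, xylan	Xyl	XylR	XylEFK,XloEFGKL,XtpEFGKL,XtpN	12	27	27	1
Inositol	Ino	IolR	InoEFGK	6	11	6	1
Maltose, maltodextrins	Mal		MalEFG	8	15	NA	1
Ribose	Rbs	RbsR	RbsABC	6	12	12	1
Glucose	Glu	GluR	GluEFK	0	4	4	1
Trehalose	Tre	TreR	TreEFG	1	5	5	1
Mannose, mannosides	Man	ManR	MtpEFGKL	7	13	11	1
Rhamnose, rhamnose oligosaccharides	Rha	RhaR	RtpEFGKL	8	14	14	1
Arabitol, mannitol	Pol			3	3	NA	1
Hypothetical sugar utilization	HSU	UgtR,UctR,UgpR	UgtEFGK,UctMPQ,UgpEFG	11	24	20	1
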