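tf	family	effector	effector_status	motif_width
AraR	GntR	arabinose	predicted	NA
BglR	ROK	cellobiose,glucose	validated	NA
CelR	LacI	cellobiose	predicted	NA
ChiR	ROK	chitobiose	validated	NA
FruR	DeoR	fructose	predicted	NA
GalR	LacI	galactose	predicted	NA
GloR	LacI	unknown	unknown	NA
GlpP	RNA-antiterminator	glycerol	predicted	NA
GluR	ROK	glucose	validated	NA
IolR	ROK	unknown	tested-none	NA
KdgR	IclR	unknown	predicted	NA
ManR	ROK	mannose	validated	NA
RbsR	LacI	ribose,ribose-5-phosphate	predicted	NA
RhaR	DeoR	rhamnose	predicted	NA
TreR	ROK	trehalose	validated	NA
UctR	NA	unknown	unknown	NA
UgpR	NA	unknown	unknown	NA
UgtR	NA	unknown	unknown	NA
UxaR	GntR	unknown	tested-none	17
XylR	ROK	xylose	validated	NA
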