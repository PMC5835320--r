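label	symbol	group	source
GSH	GSH	oxidative stress response	present investigation; literature
SOD (Cu/Zn)	SOD	oxidative stress response	literature
NXN	NXN	oxidative stress response	literature
TXNRD1	TXNRD1	oxidative stress response	literature
BACH2	BACH2	oxidative stress response	literature
gamma-glutamyltransferase	GGT	oxidative stress response	literature
HO-1	HMOX1	oxidative stress response	literature
HIF-1alpha	HIF1A	oxidative stress response	literature
GST-pi	GSTP1	oxidative stress response	literature
ABCC1 (MRP1)	ABCC1	drug transport	literature
ABCC2 (MRP2)	ABCC2	drug transport	literature
ABCC4 (MRP4)	ABCC4	drug transport	literature
ASAN1	ASAN1	drug transport	literature
SMC2L1	SMC2L1	DNA repair	literature
hMSH2	MSH2	DNA repair	literature
ARHGAPAP19	ARHGAPAP19	cell cycle/proliferation	present investigation
CDKN2D	CDKN2D	cell cycle/proliferation	present investigation
PRKACA	PRKACA	cell cycle/proliferation	present investigation
TFDP2	TFDP2	cell cycle/proliferation	literature
ZNF151	ZNF151	cell cycle/proliferation	literature
p21WAF/CIP	CDKN1A	cell cycle/proliferation	literature
BTBD2	BTBD2	cell cycle/proliferation	literature
IGFBP1	IGFBP1	cell cycle/proliferation	literature
CCND1	CCND1	cell cycle/proliferation	literature
AURKB	AURKB	cell cycle/proliferation	literature
RBBP4	RBBP4	tumor suppressors/oncogenes	present investigation
CHMP1A	CHMP1A	tumor suppressors/oncogenes	present investigation
GPRC5A	GPRC5A	tumor suppressors/oncogenes	present investigation
PML/RARAalpha	PML-RARA	tumor suppressors/oncogenes	literature
p53	TP53	tumor suppressors/oncogenes	literature
EGFR	EGFR	tumor suppressors/oncogenes	literature
MYC	MYC	tumor suppressors/oncogenes	literature
CAMK4	CAMK4	signal transduction	present investigation
PPAP2C	PPAP2C	signal transduction	present investigation
PKB3	PKB3	signal transduction	present investigation
AP-1 (Fos/Jun)	AP-1	signal transduction	present investigation
DDEF2	DDEF2	signal transduction	literature
SDC1	SDC1	signal transduction	literature
SH2BP3	SH2BP3	signal transduction	literature
STMN1	STMN1	signal transduction	literature
TJP1	TJP1	signal transduction	literature
PI3K	PI3K	signal transduction	literature
PKC	PKC	signal transduction	literature
AKT	AKT	signal transduction	literature
NFKB1	NFKB1	signal transduction	literature
ME1	ME1	metabolic pathways	present investigation
COAS4	COAS4	metabolic pathways	present investigation
ALDH3A2	ALDH3A2	metabolic pathways	present investigation; literature
ALDH3A1	ALDH3A1	metabolic pathways	literature
PTPRC	PTPRC	cytoskeleton	present investigation
ABLIM1	ABLIM1	cytoskeleton	present investigation
EPB41L1	EPB41L1	cytoskeleton	present investigation
PLS1	PLS1	cytoskeleton	present investigation
ACAA2	ACAA2	cytoskeleton	literature
ARHGEF7	ARHGEF7	cytoskeleton	literature
KRT8	KRT8	cytoskeleton	literature
MYL3	MYL3	cytoskeleton	literature
ID1	ID1	apoptosis	present investigation
GRB7	GRB7	apoptosis	literature
PIGPC1	PIGPC1	apoptosis	literature
Bcl2	BCL2	apoptosis	literature
Noxa	NOXA	apoptosis	literature
Mcl-1	MCL1	apoptosis	literature
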