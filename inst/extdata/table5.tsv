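# provenance: Table 5 of the soybean seed degradome survey -- comparison of
# target annotation groups between the Williams (five seed-coat/cotyledon
# libraries) and Heinong44 (very young whole seed) datasets. One row per
# annotation, long format.
annotation	set
Alcohol/Zinc-binding dehydrogenase	williams_only
Alg9-like mannosyltransferase	williams_only
Aluminium induced protein	williams_only
Anion Exchange protein	williams_only
Ankyrin repeat containing protein	williams_only
Ataxin-2 domain containing protein	williams_only
bHLH family protein	williams_only
BRE Expressed protein	williams_only
BTB/POZ domain containing protein	williams_only
Calcineurin-like phosphoesterase	williams_only
Cellulose synthase	williams_only
Cyclin family protein	williams_only
Dynamin family protein	williams_only
EF-hand containing protein	williams_only
Elongation Factor S-II	williams_only
F-box domain containing protein	williams_only
Ferredoxin related protein	williams_only
Glyoxal oxidase related protein	williams_only
GTPase-activating protein	williams_only
Integrase domain containing protein	williams_only
lectin domain containing protein	williams_only
LRR containing protein	williams_only
mRNA capping enzyme	williams_only
NADP/FAD oxidoreductase	williams_only
NB-ARC domain containing protein	williams_only
No Functional Annotation	williams_only
PAZ domain containing protein	williams_only
Peptide transporter family protein	williams_only
Permease family protein	williams_only
PPR repeat containing protein	williams_only
Protein tyrosine kinase	williams_only
Putative methyltransferase	williams_only
Ras family protein	williams_only
Ribose 5-phosphate isomerase	williams_only
Serine protease inhibitor family	williams_only
Serine-threonine protein kinase	williams_only
START Domain containing protein	williams_only
TIR domain containing protein	williams_only
Transcription factor TFIID	williams_only
Transferase family protein	williams_only
Transmembrane protein 14 C	williams_only
Transporter family protein	williams_only
UBA domain containing protein	williams_only
Ubiquitin-protein ligase	williams_only
Uncharacterized conserved protein	williams_only
Universal stress protein family	williams_only
Polyubiquitin protein	heinong_only
Plasmamembrane protein	heinong_only
Auxin signaling F-BOX protein	heinong_only
NADP+	heinong_only
MtN19-like protein	heinong_only
Serine-type endopeptidase	heinong_only
elongation factor	heinong_only
NSF attachment protein	heinong_only
Autophagy protein	heinong_only
embryo-related protein	heinong_only
AP2 transcription factor	heinong_only
heat shock cognate protein	heinong_only
expressed protein	heinong_only
60 S ribosomal protein	heinong_only
Disulfide isomerase	heinong_only
FAD linked oxidase family protein	heinong_only
Auxin inducible transcription factor	heinong_only
ribulose-1,5-bisphosphate carboxylase	heinong_only
AGO protein	common
Auxin Response Factor	common
Copper/zinc superoxide dismutase	common
Growth Regulating Factor	common
HD-ZIP Transcription Factor	common
MYB family Transcription Factor	common
No Apical Meristem protein (NAC Family)	common
SBP domain containing protein	common
TCP family transcription factor	common
Nuclear Factor-YA	common
Zinc Finger Family protein	common
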