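# Set of 35 genes whose deletion results in n-butanol sensitivity in both
# the BY4741 and CEN.PK113-7D genetic backgrounds.
gene	functional_group	function_summary
PRE9	ubiquitin_proteasome	Alpha 3 subunit of the 20S proteasome; only nonessential proteasome subunit
UMP1	ubiquitin_proteasome	Chaperone required for correct maturation of the 20S proteasome
YLR224W	ubiquitin_proteasome	Subunit of SCF ubiquitin ligase complexes recognizing misfolded proteins
UBP3	ubiquitin_proteasome	Ubiquitin-specific protease; deubiquitination of proteins
BRE5	ubiquitin_proteasome	Cofactor of Ubp3 in deubiquitination
STP22	multivesicular_body	Component of the ESCRT-I complex; sorts ubiquitinated membrane proteins into MVBs
SNF8	multivesicular_body	Component of the ESCRT-II complex
DID4	multivesicular_body	Component of the ESCRT-III complex
BRO1	multivesicular_body	Deubiquitination in the MVB; maintains free ubiquitin pool
VPS34	trafficking	Forms complex with Vps15 synthesizing phosphatidylinositol 3-phosphate
VPS15	trafficking	Forms complex with Vps34; endosomal membrane trafficking and protein sorting
PIH1	chaperone	Component of the R2TP complex; interacts with Hsp90
SWI6	transcription	Transcription cofactor required for the unfolded protein response
GET1	trafficking	GET complex subunit; inserts tail-anchored proteins into the ER
GET2	trafficking	GET complex subunit; inserts tail-anchored proteins into the ER
VMA7	vacuole	Subunit F of the V1 domain of vacuolar H+-ATPase
VMA22	vacuole	Peripheral membrane protein required for vacuolar H+-ATPase function
SHE4	cytoskeleton	Regulates myosin function; involved in endocytosis
GND1	metabolism	6-phosphogluconate dehydrogenase; adaptation to oxidative stress
ANP1	glycosylation	Subunit of the alpha-1,6 mannosyltransferase complex; osmotic sensitivity
GEP5	mitochondria	Protein of unknown function; mitochondrial genome maintenance
THP2	transcription	THO complex subunit; transcription elongation and telomere maintenance
MFT1	transcription	THO complex subunit; transcription elongation and telomere maintenance
SLA1	cytoskeleton	Required for assembly of the cortical actin cytoskeleton
SEC28	trafficking	Epsilon-COP coatomer subunit; retrograde Golgi-to-ER traffic
MSE1	mitochondria	Mitochondrial glutamyl-tRNA synthetase
NKP2	chromosome	Nonessential kinetochore protein of the Ctf19 complex
ALD6	metabolism	Cytosolic aldehyde dehydrogenase; acetaldehyde to acetate
SNT309	splicing	Member of the NineTeen Complex; nuclear RNA splicing
REG1	signaling	Regulatory subunit of Glc7p; negative regulation of glucose-repressible genes
HTL1	chromatin	Component of the RSC chromatin remodeling complex
POL32	replication	Third subunit of DNA polymerase delta
DHH1	rna	Cytoplasmic DExD/H-box helicase; stimulates mRNA decapping
VRP1	cytoskeleton	Actin-associated protein; cytoskeletal organization and cytokinesis
HOM2	metabolism	Aspartic beta semi-aldehyde dehydrogenase; methionine/threonine biosynthesis
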