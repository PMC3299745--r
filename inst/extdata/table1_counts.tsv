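# Phylotype-by-library clone counts for the six-library copepod study
# (three antibiotic arms: Cipr, Sulf, Trim; three solvent controls: SS, Ac, DMSO;
# 30 clones per library). Three printed count cells that conflicted with the
# 30-clone library size were reconciled as round(frequency * 30 / 100):
# Cyanobacterium/SS -> 4, Phyllobacteriaceae/Sulf -> 4, Achromobacter/Sulf -> 4.
# All columns sum to 30. "nd" = not detected.
phylotype	Cipr	Sulf	Trim	SS	Ac	DMSO
Hydrogenophaga	2	2	3	15	18	19
Acidovorax	nd	nd	nd	6	3	4
Betaproteobacterium	nd	nd	nd	2	2	2
Bacteroidetes	nd	nd	nd	3	2	nd
Cyanobacterium	nd	nd	nd	4	5	5
Cardinium	24	20	22	nd	nd	nd
Phyllobacteriaceae	2	4	2	nd	nd	nd
Achromobacter	2	4	3	nd	nd	nd
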