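# Synthetic stand-in for the 48 residue property groups (the original
# published grouping is not publicly listed). Assembled from standard
# residue classifications; aromatic = HFWY. Format: group TAB residues.
hydrophobicity_polar	RKEDQN
hydrophobicity_neutral	GASTPHY
hydrophobicity_hydrophobic	CLVIMFW
volume_small	GASCTPD
volume_medium	NVEQIL
volume_large	MHKFRYW
polarity_low	LIFWCMVY
polarity_medium	PATGS
polarity_high	HQRKNED
polarizability_low	GASDT
polarizability_medium	CPNVEQIL
polarizability_high	KMHFRYW
charge_positive	KR
charge_neutral	ANCQGHILMFPSTWYV
charge_negative	DE
sstruct_helix	EALMQKRH
sstruct_strand	VIYCWFT
sstruct_coil	GNPSD
accessibility_buried	ALFCGIVW
accessibility_exposed	RKQEND
accessibility_intermediate	MSPTHY
aromatic	HFWY
aliphatic	ILV
tiny	AGS
small	ACDGNPSTV
hydrophobic_taylor	ACFGHIKLMTVWY
polar_taylor	CDEHKNQRSTWY
charged	DEHKR
positive	HKR
acidic_amide	DENQ
sulfur_containing	CM
hydroxyl_containing	STY
amide_containing	NQ
imino	P
glycine	G
cysteine	C
histidine	H
tryptophan	W
kd_hydrophobic	ACFILMV
flexible	DEGKNPQRS
rigid	CFHILMVWY
disorder_promoting	ARSQEGKP
order_promoting	WCFIYVLN
hbond_donor	RKWNQHSTY
hbond_acceptor	DENQHSTY
helix_breaker	PG
beta_branched	ITV
long_sidechain	RKEQM
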