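# Pigment/lipid class registry: class, comma-separated chemical component
# ids, Mg atom name ("." for none), comma-separated conjugated atom names.
#
# Chlorophyll conjugated set = chlorin macrocycle pi system of the CLA/CHL
# component definitions (chemical component dictionary naming): the four
# pyrrole nitrogens, the sixteen pyrrole-ring carbons, the four methine
# bridges, the 3-vinyl substituent (CAB/CBB), and the cross-conjugated
# 13(1) keto group of ring E (CAD/OBD); for chlorophyll b additionally the
# 7-formyl group (CAB2/OMB where present). Mg, methyls, propionate and the
# phytyl tail are excluded: edge-to-edge means closest approach of the pi
# systems. Names absent from a given residue are simply not used.
#
# Carotenoid conjugated set: the sentinel ALL_C selects every carbon atom
# (polyene chain plus ring carbons); hydroxyl/epoxide oxygens excluded.
#
# Lipid classes have no conjugated set; their centroid is over all heavy
# atoms. Component-id synonyms for lipid dialects are config, not code.
CHL_A	CLA	MG	NA,NB,NC,ND,C1A,C2A,C3A,C4A,C1B,C2B,C3B,C4B,C1C,C2C,C3C,C4C,C1D,C2D,C3D,C4D,CHA,CHB,CHC,CHD,CAB,CBB,CAD,OBD
CHL_B	CHL	MG	NA,NB,NC,ND,C1A,C2A,C3A,C4A,C1B,C2B,C3B,C4B,C1C,C2C,C3C,C4C,C1D,C2D,C3D,C4D,CHA,CHB,CHC,CHD,CAB,CBB,CAD,OBD,OMB
CAR_BCR	BCR	.	ALL_C
CAR_LUT	LUT	.	ALL_C
CAR_VIO	XAT,VIO	.	ALL_C
LIPID_PG	LHG,PG	.	.
LIPID_MGDG	LMG,LMT	.	.
LIPID_DGDG	DGD,DGA	.	.
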