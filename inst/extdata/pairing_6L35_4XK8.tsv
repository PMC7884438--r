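# Antenna-site pairing between the moss (6L35, reference) and pea
# (4XK8, mobile) PSI-LHCI belts. The second Lhca position is occupied
# by Lhca5 in the moss and Lhca4 in the pea; sites are paired by belt
# position, never by subunit name alone.
site	ref_subunit	mob_subunit
pos1	Lhca1	Lhca1
pos2	Lhca5	Lhca4
pos3	Lhca2	Lhca2
pos4	Lhca3	Lhca3
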