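# Subunit map for the moss PSI-LHCI entry 6L35.
# Chain labels follow the conventional PSI-LHCI deposition scheme
# (core subunits on their letter chains, antenna sites on chains 1-4 in
# belt order Lhca1-Lhca5-Lhca2-Lhca3). Chain labels are checked against
# the loaded model at apply time: entries naming absent chains warn and
# are ignored, chains left unmapped warn and become "unknown" -- verify
# against the deposit's entity annotations before quantitative use.
6L35 A PsaA
6L35 B PsaB
6L35 C PsaC
6L35 D PsaD
6L35 E PsaE
6L35 F PsaF
6L35 G PsaG
6L35 H PsaH
6L35 I PsaI
6L35 J PsaJ
6L35 K PsaK
6L35 L PsaL
6L35 M PsaM
6L35 1 Lhca1
6L35 2 Lhca5
6L35 3 Lhca2
6L35 4 Lhca3
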