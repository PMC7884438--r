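# Subunit map for the pea PSI-LHCI entry 4XK8 (conventional chain
# labelling; same validation caveat as the 6L35 map).
4XK8 A PsaA
4XK8 B PsaB
4XK8 C PsaC
4XK8 D PsaD
4XK8 E PsaE
4XK8 F PsaF
4XK8 G PsaG
4XK8 H PsaH
4XK8 I PsaI
4XK8 J PsaJ
4XK8 K PsaK
4XK8 L PsaL
4XK8 1 Lhca1
4XK8 2 Lhca4
4XK8 3 Lhca2
4XK8 4 Lhca3
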