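# Subunit map for the C. reinhardtii PSI-LHCI entry 6IJO (conventional
# chain labelling; same validation caveat as the 6L35 map). The green
# algal belt carries up to ten Lhca subunits; only the inner-belt sites
# comparable to the four-site moss/plant belt are mapped here.
6IJO A PsaA
6IJO B PsaB
6IJO C PsaC
6IJO D PsaD
6IJO E PsaE
6IJO F PsaF
6IJO G PsaG
6IJO H PsaH
6IJO I PsaI
6IJO J PsaJ
6IJO K PsaK
6IJO L PsaL
6IJO 1 Lhca1
6IJO 2 Lhca8
6IJO 3 Lhca7
6IJO 4 Lhca3
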