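# Small excerpt of printed human-liver reaction equations (native format).
# Substrate-cycle demonstrations: fructose phosphorylation/dephosphorylation,
# glutathione synthesis/degradation, acetyl-CoA activation, and reversible
# mitochondria-cytosol antiport of TCA intermediates and inorganic ions.
r0736	ATP(c) + Fructose-6P(c) --> ADP(c) + Fructose-1,6PP(c)
r0487	Fructose-1,6PP(c) + H2O(c) --> Fructose-6P(c) + Pi(c)
r0129	GSH(c) + H2O(c) <=> Glutamate(c) + Cys-Gly(c)
r0131	ATP(c) + gamma-Glutamyl-cysteine(c) + Glycine(c) --> ADP(c) + Pi(c) + GSH(c)
r0212	ATP(c) + Glutamate(c) + Cysteine(c) --> ADP(c) + Pi(c) + gamma-Glutamyl-cysteine(c)
r0214	H2O(c) + Cys-Gly(c) <=> Cysteine(c) + Glycine(c)
r0829	Succinate(c) + Sulfate(m) <=> Succinate(m) + Sulfate(c)
r0831	Malate(c) + Pi(m) <=> Malate(m) + Pi(c)
r0931	Isocitrate(m) + Malate(c) <=> Isocitrate(c) + Malate(m)
r0915	Citrate(c) + Succinate(m) <=> Citrate(m) + Succinate(c)
r0917	Citrate(c) + Isocitrate(m) <=> Citrate(m) + Isocitrate(c)
r0066	ATP(c) + Acetate(c) + CoA(c) --> AMP(c) + PPi(c) + Acetyl-CoA(c)
r0485	Glucosamine-6P(c) + Acetyl-CoA(c) --> CoA(c) + N-Acetylglucosamine-6P(c)
r0486	N-Acetylglucosamine-6P(c) + H2O(c) <=> Glucosamine-6P(c) + Acetate(c)
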