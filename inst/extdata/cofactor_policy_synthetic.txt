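# Synthetic reconstruction of a typical compartmentalized cofactor list:
# energy/redox carriers stripped for EFM analysis only; inorganic species
# stripped for both EFM and ShReD analysis. Not a published model's curated list.
[efm_removed]
ATP(c)
ADP(c)
AMP(c)
NADH(c)
NAD+(c)
NADPH(c)
NADP+(c)
FADH2(c)
FAD(c)
ATP(m)
ADP(m)
AMP(m)
NADH(m)
NAD+(m)
NADPH(m)
NADP+(m)
FADH2(m)
FAD(m)
ATP(r)
ADP(r)
AMP(r)
NADH(r)
NAD+(r)
NADPH(r)
NADP+(r)
FADH2(r)
FAD(r)
ATP(p)
ADP(p)
AMP(p)
NADH(p)
NAD+(p)
NADPH(p)
NADP+(p)
FADH2(p)
FAD(p)
ATP(n)
ADP(n)
AMP(n)
NADH(n)
NAD+(n)
NADPH(n)
NADP+(n)
FADH2(n)
FAD(n)
ATP(x)
ADP(x)
AMP(x)
NADH(x)
NAD+(x)
NADPH(x)
NADP+(x)
FADH2(x)
FAD(x)
H2O(c)
H+(c)
Pi(c)
PPi(c)
Sulfate(c)
Sulfite(c)
O2(c)
CO2(c)
HCO3-(c)
H2O(m)
H+(m)
Pi(m)
PPi(m)
Sulfate(m)
Sulfite(m)
O2(m)
CO2(m)
HCO3-(m)
H2O(r)
H+(r)
Pi(r)
PPi(r)
Sulfate(r)
Sulfite(r)
O2(r)
CO2(r)
HCO3-(r)
H2O(p)
H+(p)
Pi(p)
PPi(p)
Sulfate(p)
Sulfite(p)
O2(p)
CO2(p)
HCO3-(p)
H2O(n)
H+(n)
Pi(n)
PPi(n)
Sulfate(n)
Sulfite(n)
O2(n)
CO2(n)
HCO3-(n)
H2O(x)
H+(x)
Pi(x)
PPi(x)
Sulfate(x)
Sulfite(x)
O2(x)
CO2(x)
HCO3-(x)
[shred_removed]
H2O(c)
H+(c)
Pi(c)
PPi(c)
Sulfate(c)
Sulfite(c)
O2(c)
CO2(c)
HCO3-(c)
H2O(m)
H+(m)
Pi(m)
PPi(m)
Sulfate(m)
Sulfite(m)
O2(m)
CO2(m)
HCO3-(m)
H2O(r)
H+(r)
Pi(r)
PPi(r)
Sulfate(r)
Sulfite(r)
O2(r)
CO2(r)
HCO3-(r)
H2O(p)
H+(p)
Pi(p)
PPi(p)
Sulfate(p)
Sulfite(p)
O2(p)
CO2(p)
HCO3-(p)
H2O(n)
H+(n)
Pi(n)
PPi(n)
Sulfate(n)
Sulfite(n)
O2(n)
CO2(n)
HCO3-(n)
H2O(x)
H+(x)
Pi(x)
PPi(x)
Sulfate(x)
Sulfite(x)
O2(x)
CO2(x)
HCO3-(x)
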