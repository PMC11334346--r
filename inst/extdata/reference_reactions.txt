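# Redox reactions of the CO-fed TCE-dechlorinating system.
# Grammar: name: coef species(phase) + ... -> coef species(phase) + ...
dechlorination: TCE(aq) + 3 H2(g) -> ethene(g) + 3 HCl
wgs: CO(g) + water(l) -> CO2(g) + H2(g)
acetogenesis_h2: 2 CO2(g) + 4 H2(g) -> 2 water(l) + CH3COOH
acetogenesis_co: 4 CO(g) + 2 water(l) -> 2 CO2(g) + CH3COOH
methanogenesis_ac: CH3COOH -> CO2(g) + CH4(g)
methanogenesis_h2: CO2(g) + 4 H2(g) -> 2 water(l) + CH4(g)
methanogenesis_co: 4 CO(g) + 2 water(l) -> 3 CO2(g) + CH4(g)
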