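name,formula,phase,dfG_kJ_per_mol,source
CO,CO,gas,-137.2,CRC Handbook 84th ed.
CO2,CO2,gas,-394.4,CRC Handbook 84th ed.
H2,H2,gas,0,CRC Handbook 84th ed.
water,H2O,liquid,-237.1,CRC Handbook 84th ed.
methane,CH4,gas,-50.5,CRC Handbook 84th ed.
ethene,C2H4,gas,68.4,CRC Handbook 84th ed.
acetic_acid,C2H4O2,liquid,-389.9,CRC Handbook 84th ed.
TCE,C2HCl3,aqueous,NA,
cDCE,C2H2Cl2,aqueous,NA,
VC,C2H3Cl,aqueous,NA,
HCl,HCl,aqueous,NA,
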