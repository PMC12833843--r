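name,n_pa,provenance
Xyl,5,printed hydration table
Fuc,5,derived: 5 oxygens (4 OH + ring O)
Glc,6,printed hydration table
Gal,6,printed hydration table
GlcA,7,derived: 7 oxygens; carboxylate counted as two polar atoms
GlcNAc,7,derived: 6 oxygens + amide counted as two polar atoms
GalNAc,7,derived: 6 oxygens + amide counted as two polar atoms
Neu5Ac,10,derived: 9 oxygens with carboxylate and amide each counted as two polar atoms
trehalose,11,printed hydration table
sucrose,11,printed hydration table
lactose,10,printed hydration table
maltose,10,printed hydration table
cellobiose,10,printed hydration table
tetra-O-Ac-Glc-a-OMe,9,derived: 4 ester groups counted as two polar atoms each + ring O; consistent with the printed empirical D (the methyl ether O appears uncounted)
maltotriose,16,printed hydration table
cellotriose,16,derived: 16 oxygens (isomer of maltotriose)
maltohexaose,31,printed hydration table
maltoheptaose,36,derived: all 36 oxygens
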