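# Quasi-equilibrium scenario: methyl-reducing methanogenesis from methanol.
#
# The methyl group enters coenzyme M directly from environmental methanol
# through the methanol:coenzyme-M methyltransferase system (MtaB/MtaA,
# collapsed into one net reaction; the cobamide carrier cancels out).
# Methanol is a boundary species held at a low nanomolar concentration
# typical of marine sediment porewater, the scarce-substrate regime of
# methyl-reducing methanogens; cofactor pool totals match the companion
# CO2-reduction scenario. The terminal reductase is again the dissipative
# sink at fixed negative dG.
name: methanol_reduction
temperature: 298.15
species:
  - {name: CH3OH,       phase: aqueous, role: boundary,  value: 7.5e-5}   # 75 nM
  - {name: CH4,         phase: gas,     role: boundary,  value: 0.5}
  - {name: H2O,         phase: aqueous, role: boundary,  value: 1000}     # activity 1
  - {name: HS-CoM,      phase: aqueous, role: cofactor,  value: 1.25}
  - {name: CH3-S-CoM,   phase: aqueous, role: cofactor,  value: 1.25}
  - {name: HS-CoB,      phase: aqueous, role: cofactor,  value: 0.5}
  - {name: CoM-S-S-CoB, phase: aqueous, role: cofactor,  value: 0.5}
pools:
  - {name: coenzyme-M, members: [HS-CoM, CH3-S-CoM],    total: 2.5}
  - {name: coenzyme-B, members: [HS-CoB, CoM-S-S-CoB],  total: 1.0}
reactions:
  - {name: Mta, equation: "CH3OH + HS-CoM -> CH3-S-CoM + H2O",        dg0: -27.5, mode: equilibrium, adjust: CH3-S-CoM}
  - {name: Mcr, equation: "CH3-S-CoM + HS-CoB -> CH4 + CoM-S-S-CoB",  dg0: -45.0, mode: fixed, target: -30.0, adjust: CoM-S-S-CoB}
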