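# Quasi-equilibrium scenario: CO2-reducing (hydrogenotrophic) methanogenesis.
#
# Standard transformed Gibbs energies (dg0, kJ/mol, pH 7, 1 M / 1 atm
# standard states, water activity 1, protons absorbed into dG0') are the
# commonly compiled values for the individual enzymatic steps of the
# archaeal methyl branch of the Wood-Ljungdahl pathway and downstream
# methyl transfer. Boundary conditions and cofactor pool totals are data,
# not code: they encode one H2-rich scenario (hydrothermal-type habitat,
# pH2 = 0.01 atm) with intracellular cofactor totals in the range reported
# for methanogens. Every step runs at equilibrium (dG = 0) except the
# terminal methyl-S-CoM reductase step, which is the dissipative sink and
# is held at a fixed negative dG.
name: co2_reduction
temperature: 298.15
species:
  - {name: H2,          phase: gas,     role: boundary,     value: 0.01}
  - {name: CO2,         phase: gas,     role: boundary,     value: 0.2}
  - {name: CH4,         phase: gas,     role: boundary,     value: 0.5}
  - {name: H2O,         phase: aqueous, role: boundary,     value: 1000}   # activity 1
  - {name: MFR,         phase: aqueous, role: cofactor,     value: 1.4}
  - {name: CHO-MFR,     phase: aqueous, role: cofactor,     value: 0.1}
  - {name: H4MPT,       phase: aqueous, role: cofactor,     value: 1.6}
  - {name: CHO-H4MPT,   phase: aqueous, role: cofactor,     value: 0.1}
  - {name: CH-H4MPT,    phase: aqueous, role: cofactor,     value: 0.1}   # methenyl
  - {name: CH2-H4MPT,   phase: aqueous, role: cofactor,     value: 0.1}   # methylene
  - {name: CH3-H4MPT,   phase: aqueous, role: cofactor,     value: 0.1}   # methyl
  - {name: F420,        phase: aqueous, role: cofactor,     value: 0.25}
  - {name: F420H2,      phase: aqueous, role: cofactor,     value: 0.25}
  - {name: HS-CoM,      phase: aqueous, role: cofactor,     value: 1.25}
  - {name: CH3-S-CoM,   phase: aqueous, role: cofactor,     value: 1.25}
  - {name: HS-CoB,      phase: aqueous, role: cofactor,     value: 0.5}
  - {name: CoM-S-S-CoB, phase: aqueous, role: cofactor,     value: 0.5}
pools:
  - {name: methanofuran,  members: [MFR, CHO-MFR],                                       total: 1.5}
  - {name: methanopterin, members: [H4MPT, CHO-H4MPT, CH-H4MPT, CH2-H4MPT, CH3-H4MPT],   total: 2.0}
  - {name: F420-couple,   members: [F420, F420H2],                                       total: 0.5}
  - {name: coenzyme-M,    members: [HS-CoM, CH3-S-CoM],                                  total: 2.5}
  - {name: coenzyme-B,    members: [HS-CoB, CoM-S-S-CoB],                                total: 1.0}
reactions:
  # F420 redox couple pinned by equilibrium with the H2 partial pressure
  - {name: Frh, equation: "F420 + H2 -> F420H2",                       dg0: -11.1, mode: equilibrium, adjust: F420H2}
  - {name: Fmd, equation: "CO2 + H2 + MFR -> CHO-MFR + H2O",           dg0:  16.0, mode: equilibrium, adjust: CHO-MFR}
  - {name: Ftr, equation: "CHO-MFR + H4MPT -> CHO-H4MPT + MFR",        dg0:  -4.4, mode: equilibrium, adjust: CHO-H4MPT}
  - {name: Mch, equation: "CHO-H4MPT -> CH-H4MPT + H2O",               dg0:  -4.6, mode: equilibrium, adjust: CH-H4MPT}
  - {name: Mtd, equation: "CH-H4MPT + F420H2 -> CH2-H4MPT + F420",     dg0:   6.5, mode: equilibrium, adjust: CH2-H4MPT}
  - {name: Mer, equation: "CH2-H4MPT + F420H2 -> CH3-H4MPT + F420",    dg0:  -5.2, mode: equilibrium, adjust: CH3-H4MPT}
  - {name: Mtr, equation: "CH3-H4MPT + HS-CoM -> CH3-S-CoM + H4MPT",   dg0: -30.0, mode: equilibrium, adjust: CH3-S-CoM}
  # terminal reductase: dissipative sink, held 30 kJ/mol below standard
  - {name: Mcr, equation: "CH3-S-CoM + HS-CoB -> CH4 + CoM-S-S-CoB",   dg0: -45.0, mode: fixed, target: -30.0, adjust: CoM-S-S-CoB}
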