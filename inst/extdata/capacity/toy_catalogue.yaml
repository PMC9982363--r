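# Tiny pathway catalogue used in examples and tests. The "genes" entries
# are gene-family ids; a nested list is an isoenzyme alternative group
# that counts as a single gene for the size rule.
pathways:
  - id: ser
    category: amino-acid
    compound: serine
    genes: [famA1, famA2, famA3]
  - id: thr
    category: amino-acid
    compound: threonine
    genes: [famB1, famB2, famB3, famB4, famB5]
  - id: trp
    category: amino-acid
    compound: tryptophan
    genes: [famC1, famC2, famC3, famC4, famC5, famC6, famC7]
  - id: f430
    category: vitamin-cofactor
    compound: cofactor F430
    genes: [cfbA, cfbB, cfbC, cfbD, cfbE]
  - id: f420
    category: vitamin-cofactor
    compound: coenzyme F420
    genes: [cofC, cofD, cofE, cofG, [cofH1, cofH2], cofX]
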