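# Lipopeptide family template registry.
#
# positions: fixed residue per position ("*" = variable); the acyl chain
# counts as position 1 of the molecule, residues are numbered 1..L here.
# canonical: the concrete residues used by the spectrum simulator.
# Iturin and fengycin are incomplete stubs (no positions): they are skipped
# by the classifier until a user completes them.
- name: Surfactin
  cyclic: true
  lipid_range: [10, 17]
  variable_domain: ["Leu/Ile", "Val"]
  positions: ["Glu", "*", "Leu", "*", "Asp", "Leu", "*"]
  canonical: ["Glu", "Leu/Ile", "Leu", "Val", "Asp", "Leu", "Leu/Ile"]
- name: Iturin
  cyclic: true
  lipid_range: [14, 17]
- name: Fengycin
  cyclic: true
  lipid_range: [14, 18]
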