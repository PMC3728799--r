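# Acid-base species registry for dissolution-medium chemistry.
# pKa values are standard 25 degC reference values; phosphate species share
# the "phosphate" family so their totals pool into one speciation problem.
HCl:
  type: strong_acid
  pKa: []
  charge_fully_protonated: 0
  counterion_charge: 0
  conjugate_charge: -1
  form_names: ["Cl-"]
NaOH:
  type: strong_base
  pKa: []
  charge_fully_protonated: 0
  counterion_charge: 1
Na3PO4:
  type: polyprotic_acid_salt
  family: phosphate
  pKa: [2.148, 7.198, 12.35]
  charge_fully_protonated: 0
  counterion_charge: 3
  form_names: ["H3PO4", "H2PO4-", "HPO4-2", "PO4-3"]
Na2HPO4:
  type: polyprotic_acid_salt
  family: phosphate
  pKa: [2.148, 7.198, 12.35]
  charge_fully_protonated: 0
  counterion_charge: 2
  form_names: ["H3PO4", "H2PO4-", "HPO4-2", "PO4-3"]
NaH2PO4:
  type: polyprotic_acid_salt
  family: phosphate
  pKa: [2.148, 7.198, 12.35]
  charge_fully_protonated: 0
  counterion_charge: 1
  form_names: ["H3PO4", "H2PO4-", "HPO4-2", "PO4-3"]
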