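# Demo run configuration: the synthetic ground-truth physiology and the
# default calibrate-once-predict-twice study. Keys embed their units.
physiology:
  V_gics_L: 1.0
  V_liver_L: 1.8
  V_plasma_L: 10
  V_tissues_L: 35
  V_lumen_stomach_L: 0.25
  V_lumen_si_L: 0.4
  V_lumen_li_L: 0.3
  Q_gics_L_per_h: 60
  Q_portal_L_per_h: 60
  Q_hepatic_out_L_per_h: 60
  Q_tissues_L_per_h: 20
  k_gastric_per_h: 2.8
  k_si_transit_per_h: 0.25
  k_li_transit_per_h: 0.05
  PA_stomach_L_per_h: 0.02
  PA_si_L_per_h: 2.5
  PA_li_L_per_h: 0.3
  CL_hepatic_L_per_h: 40
  CL_renal_L_per_h: 2
  F_unbound_factor: 3
  t_form_gastric_h: 2
  t_form_si_h: 3
dose:
  route: oral
  amount_mg: 100
free_parameters: [PA_si, CL_hepatic, Q_tissues, F_unbound_factor]
seed: 1
output_dir: "."
log_level: info
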