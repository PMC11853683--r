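V_ANT:
  value: 574.0
  unit: molecules/ms/um^2
  provenance: calibrated
V_AS:
  value: 298.0
  unit: molecules/ms/um^2
  provenance: calibrated
K_ADP:
  value: 0.071
  unit: mM
  provenance: calibrated
K_ATP:
  value: 24.0
  unit: mM
  provenance: calibrated
K_Pi:
  value: 2.0
  unit: mM
  provenance: calibrated
K_Ca_ATP:
  value: 0.165
  unit: mM
  provenance: calibrated
K_V_ATP:
  value: 131.0
  unit: mV
  provenance: calibrated
psi_m:
  value: 172.0
  unit: mV
  provenance: printed
f_P:
  value: 0.5
  unit: dimensionless
  provenance: printed
T:
  value: 310.0
  unit: K
  provenance: assumed-physiological
f_ADP3_m:
  value: 0.45
  unit: dimensionless
  provenance: calibrated
f_ADP3_e:
  value: 0.45
  unit: dimensionless
  provenance: calibrated
f_ATP4_m:
  value: 0.05
  unit: dimensionless
  provenance: calibrated
f_ATP4_e:
  value: 0.0365
  unit: dimensionless
  provenance: calibrated
Pi_m:
  value: 2.0
  unit: mM
  provenance: calibrated
Pi_e:
  value: .na
  unit: mM
  provenance: equilibrium-convention
Ca_m:
  value: 0.4
  unit: mM
  provenance: calibrated
k_f:
  value: 0.009
  unit: 1/ms
  provenance: printed
k_r:
  value: 1.0
  unit: 1/mM/ms
  provenance: printed
D_ADP:
  value: 0.028
  unit: um^2/ms
  provenance: calibrated
D_ATP:
  value: 0.028
  unit: um^2/ms
  provenance: calibrated
as_denominator:
  value: grouped
  unit: choice
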