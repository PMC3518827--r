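# Published acute-mediastinitis recovery-prediction scale: means/SDs of
# the eight admission parameters in the derivation cohort (n = 44),
# varimax-rotated factor weights, per-factor recovery thresholds and
# the default vote-combination rule.
name: published acute mediastinitis recovery scale
parameters: [hgb, proteins, coex_diseases, wbc_pre, age, albumins, crp_pre, pct_pre]
factor_names: [proteinic status, inflammatory status, general risk]
means: [11.5677, 57.3864, 1.97727, 15.2432, 52.5455, 31.6773, 202.891, 2.93409]
sds: [2.14823, 7.35118, 1.42223, 5.14417, 13.7595, 3.90652, 50.1198, 3.92167]
weights:
  F1: [0.712131, 0.854481, -0.131796, 0.00534419, -0.141942, 0.908303, -0.651832, -0.560482]
  F2: [0.152337, -0.0461529, -0.0604516, 0.914729, 0.263779, -0.0949298, 0.514794, 0.371643]
  F3: [-0.243032, -0.0418942, 0.863627, 0.108861, 0.685527, -0.167625, 0.0364827, 0.141625]
thresholds:
  - {cutoff: -1.4, recovery_side: above}
  - {cutoff: 1.0, recovery_side: below}
  - {cutoff: 0.4, recovery_side: below}
combination: majority
provenance: >-
  Constants transcribed from the published derivation study of the
  scale (44 consecutive acute mediastinitis patients); decimal commas
  converted to dots, values otherwise unmodified.
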