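# Varimax-rotated factor weight matrix of the published acute
# mediastinitis recovery scale (columns F1 proteinic status, F2
# inflammatory status, F3 general risk), with the published
# communality and specific-variance values for each parameter.
parameter,F1,F2,F3,communality,specific_variance
hgb,0.712131,0.152337,-0.243032,0.589401,0.410599
proteins,0.854481,-0.0461529,-0.0418942,0.734023,0.265977
coex_diseases,-0.131796,-0.0604516,0.863627,0.766875,0.233125
wbc_pre,0.00534419,0.914729,0.108861,0.848609,0.151391
age,-0.141942,0.263779,0.685527,0.559674,0.440326
albumins,0.908303,-0.0949298,-0.167625,0.862124,0.137876
crp_pre,-0.651832,0.514794,0.0364827,0.691229,0.308771
pct_pre,-0.560482,0.371643,0.141625,0.472317,0.527683
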