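# Standardization constants (mean, sample SD) of the eight admission
# parameters in the published 44-patient acute mediastinitis cohort.
# Row order is the canonical parameter order shared across the package.
parameter,mean,sd
hgb,11.5677,2.14823
proteins,57.3864,7.35118
coex_diseases,1.97727,1.42223
wbc_pre,15.2432,5.14417
age,52.5455,13.7595
albumins,31.6773,3.90652
crp_pre,202.891,50.1198
pct_pre,2.93409,3.92167
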