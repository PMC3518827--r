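# Published eigenvalue table of the principal-component extraction on
# the 8x8 correlation matrix of the acute mediastinitis cohort
# (initial communalities all 1; factors with eigenvalue > 1 retained).
component,eigenvalue,percent_variance,cumulative_percent
1,3.31109,41.389,41.389
2,1.16325,14.541,55.929
3,1.04991,13.124,69.053
4,0.754858,9.436,78.489
5,0.682004,8.525,87.014
6,0.540662,6.758,93.772
7,0.358296,4.479,98.251
8,0.139929,1.749,100.000
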