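zone,tissue,mean_kbq_ml,ci_lo,ci_hi,sd
1,lung_air,0.62,0.52,0.72,0.44
2,adipose,1.32,1.15,1.49,0.73
3,soft_tissue,3.52,3.09,3.96,1.92
4,spongy_bone,27.5,24.9,30.0,11.3
5,cortical_bone,44.3,38.8,49.8,24.1
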