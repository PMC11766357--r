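feature,fc,p,auc,sn,sp,ppv,npv,n_pos,n_neg
hsa-miR-30a-3p,-4.96,0.03,0.80,0.94,0.59,0.70,0.91,17,17
hsa-miR-374a-5p,-9.93,0.00,0.78,1.00,0.47,0.65,1.00,17,17
hsa-miR-15a-5p,3.76,0.02,0.76,0.71,0.71,0.71,0.71,17,17
hsa-let-7d-5p,1.48,0.03,0.75,0.82,0.65,0.70,0.79,17,17
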