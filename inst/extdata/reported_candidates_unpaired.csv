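feature,fc,p,auc,sn,sp,ppv,npv,n_pos,n_neg
hsa-let-7d-5p,-1.76,0.01,0.81,0.72,0.83,0.87,0.67,18,12
hsa-miR-224-5p,-13.00,0.01,0.78,0.94,0.58,0.77,0.88,18,12
hsa-miR-221-3p,-5.06,0.04,0.78,0.78,0.67,0.78,0.67,18,12
Leu_Comb_5,4.08,0.04,0.78,0.83,0.75,0.83,0.75,18,12
Ser_Comb_22,6.50,0.01,0.76,0.89,0.58,0.76,0.78,18,12
hsa-miR-10b-5p,1.73,0.01,0.76,0.89,0.58,0.76,0.78,18,12
hsa-miR-125a-5p,1.47,0.02,0.76,0.67,0.92,0.92,0.65,18,12
hsa-miR-191-5p,-1.35,0.04,0.75,1.00,0.50,0.75,1.00,18,12
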