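table,parameter,mfe,rmse
table4_iv,auc_inf,0.91,46.2
table4_iv,cmax,1.00,6.76
table4_iv,cl,1.01,1.38
table5_oral,auc_inf,0.99,27.27
table5_oral,cmax,1.03,1.66
table5_oral,cl,0.99,1.96
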