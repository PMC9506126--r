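group,parameter,predicted,observed,fold_error
control,auc_inf,174,186.1,0.93
control,t_half,11.5,10.1,1.22
rifampicin,auc_inf,103.85,105.03,0.99
rifampicin,t_half,4.76,4.93,0.97
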