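scenario_id,parameter,predicted,observed,ratio,pe_percent,obs_pk_solver
oral_0.503mgkg_healthy_40,auc_inf,537.4,566,0.95,5.1,FALSE
oral_0.503mgkg_healthy_40,cmax,33.60,37.4,0.90,10.2,TRUE
oral_0.503mgkg_healthy_40,cl,15.61,15.41,1.01,1.3,TRUE
oral_0.5mgkg_healthy_41,auc_inf,544,500.1,1.10,8.8,TRUE
oral_0.5mgkg_healthy_41,cmax,35.34,35.83,0.99,1.3,TRUE
oral_0.5mgkg_healthy_41,cl,15.20,16.64,0.91,8.7,TRUE
oral_0.5mgkg_psych_42,auc_inf,550,512.6,1.07,7.3,FALSE
oral_0.5mgkg_psych_42,cmax,20.81,19.76,1.05,5.3,TRUE
oral_0.5mgkg_psych_42,cl,15.12,15.73,0.96,3.9,TRUE
oral_10mg_psych_48,auc_inf,212.8,200.5,1.06,6.1,FALSE
oral_10mg_psych_48,cmax,9.13,8.34,1.08,9.5,TRUE
oral_10mg_psych_48,cl,15,18.2,0.82,17.6,FALSE
oral_5mg_healthy_49,auc_inf,40.10,44,0.91,8.9,TRUE
oral_5mg_healthy_49,cmax,1.28,1.27,1.01,0.8,TRUE
oral_5mg_healthy_49,cl,29.0,25.85,1.12,12.2,TRUE
oral_2mg_psych_46,auc_inf,90.73,103,0.88,12,TRUE
oral_2mg_psych_46,cmax,3.95,3.54,1.12,11.6,TRUE
oral_2mg_psych_46,cl,5.50,4.93,1.12,11.7,TRUE
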