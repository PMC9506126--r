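scenario_id,parameter,predicted,observed,ratio,pe_percent,obs_pk_solver
iv_0.125mgkg_healthy_40,auc_inf,168,202,0.83,17,FALSE
iv_0.125mgkg_healthy_40,cmax,28,27,1.04,4,TRUE
iv_0.125mgkg_healthy_40,cl,12.3,11.1,1.11,9.3,FALSE
iv_0.125mgkg_healthy_41,auc_inf,171.3,173.3,1.01,1.2,TRUE
iv_0.125mgkg_healthy_41,cmax,32.5,32.5,1.00,0.00,TRUE
iv_0.125mgkg_healthy_41,cl,12.0,12.02,0.99,0.00,TRUE
iv_0.125mgkg_psych_42,auc_inf,271,383,0.71,6.3,FALSE
iv_0.125mgkg_psych_42,cmax,77.22,63.10,1.22,22.4,TRUE
iv_0.125mgkg_psych_42,cl,7.56,6.20,1.22,21.9,FALSE
iv_10mg_healthy_43,auc_inf,193,202,0.96,4.5,TRUE
iv_10mg_healthy_43,cmax,31.50,25.70,1.21,23,TRUE
iv_10mg_healthy_43,cl,12.20,11.90,1.03,2.5,TRUE
iv_5mg_psych_44,auc_inf,97.56,86.20,1.13,13.2,TRUE
iv_5mg_psych_44,cmax,108.70,115,0.95,5.5,TRUE
iv_5mg_psych_44,cl,10,13,0.77,23,TRUE
iv_3.5mg_psych_46,auc_inf,144.30,175.72,0.82,18,TRUE
iv_3.5mg_psych_46,cmax,15.13,19.2,0.79,21.2,TRUE
iv_3.5mg_psych_46,cl,6.30,6.50,0.97,3.1,FALSE
iv_2.5mg_healthy_47,auc_inf,56,60.40,0.93,7.3,FALSE
iv_2.5mg_healthy_47,cmax,22.00,27.43,0.80,19.8,TRUE
iv_2.5mg_healthy_47,cl,10.62,11.55,0.92,8.2,TRUE
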