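scenario_id,compound,route,dose,dose_unit,n,n_female,age,weight,population,ref
iv_0.125mgkg_healthy_40,haloperidol,iv,0.125,mg/kg,6,0,21-37,mean 70.5,healthy,40
iv_0.125mgkg_healthy_41,haloperidol,iv,0.125,mg/kg,12,0,19-37,56-92,healthy,41
iv_0.125mgkg_psych_42,haloperidol,iv,0.125,mg/kg,8,0,21-48,mean 63.3,psychotic otherwise healthy,42
iv_10mg_healthy_43,haloperidol,iv,10,mg,12,0,,,healthy,43
iv_5mg_psych_44,haloperidol,iv,5,mg,1,1,mean 55,74,psychotic otherwise healthy,44
iv_5mg_tb_control_45,haloperidol,iv,5,mg,2,,20s-60s,,tuberculotic control,45
iv_5mg_tb_rifampicin_45,haloperidol,iv,5,mg,3,,20s-60s,,tuberculotic intervention,45
iv_3.5mg_psych_46,haloperidol,iv,3.5,mg,6,3,20-43,mean 67,psychotic otherwise healthy,46
iv_2.5mg_healthy_47,haloperidol,iv,2.5,mg,4,2,24-37,63-82,healthy,47
rhal_after_iv_0.125mgkg_42,reduced haloperidol,iv,0.125,mg/kg,8,0,21-48,mean 63.3,psychotic otherwise healthy,42
oral_0.503mgkg_healthy_40,haloperidol,oral,0.503,mg/kg,8,0,19-37,mean 70.8,healthy,40
oral_0.5mgkg_healthy_41,haloperidol,oral,0.500,mg/kg,9,0,19-37,56-92,healthy,41
oral_0.5mgkg_psych_42,haloperidol,oral,0.500,mg/kg,6,0,21-48,mean 63.3,psychotic otherwise healthy,42
oral_10mg_psych_48,haloperidol,oral,10,mg,6,0,32-57,43-66,psychotic otherwise healthy,48
oral_5mg_healthy_49,haloperidol,oral,5,mg,28,0,18-50,mean 71.5,healthy,49
oral_2mg_psych_46,haloperidol,oral,2,mg,8,5,mean 32,mean 67,psychotic otherwise healthy,46
rhal_after_oral_0.5mgkg_42,reduced haloperidol,oral,0.500,mg/kg,6,0,21-48,63.3 +/- 6.7,psychotic otherwise healthy,42
rhal_oral_10mg_48,reduced haloperidol,oral,10,mg,6,0,32-57,43-66,psychotic otherwise healthy,48
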