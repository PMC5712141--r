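# Reference stroke cohort: patient characteristics and walking speeds
patient_id,sex,age_yrs,weight_kg,therapist_id,bbs_pnts,fac_pnts,speed_10mwt_mps,dgi_pnts,walking_speed_mps
1,M,60,81,1,41,3,0.17,12,0.22
2,M,56,91,1,38,3,0.46,10,0.38
3,M,64,76,2,32,3,0.31,14,0.31
4,M,54,80,3,46,4,0.85,NA,0.54
5,M,58,82,4,47,4,0.47,13,0.33
6,M,68,85,5,34,3,0.27,NA,0.28
7,M,58,79,6,44,2,0.41,16,0.20
8,M,49,98,7,46,4,0.41,12,0.30
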