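borane_id,core,aryl_variant,lumo_ev,dGw_kcal,dGh_kcal,edef_h2o_kcal,edef_thf_kcal,qB_e,qC_e,accessible
B1a,B1,a,,,,,,,,TRUE
B2a,B2,a,,,,,,,,TRUE
B3a,B3,a,,,,,,,,TRUE
B5a,B5,a,,,,,,,,TRUE
B6a,B6,a,,,,,,,,TRUE
B1v,B1,v,,,,,,,,TRUE
B1w,B1,w,,,,,,,,TRUE
BCF,BCF,,,,,,,,,TRUE
B1f,B1,f,,,,,,,,TRUE
B2b,B2,b,,,,,,,,TRUE
B2c,B2,c,,,,,,,,TRUE
B2e,B2,e,,,,,,,,TRUE
B3b,B3,b,,,,,,,,TRUE
B3c,B3,c,,,,,,,,TRUE
B3s,B3,s,,,,,,,,TRUE
B4b,B4,b,,,,,,,,TRUE
B4c,B4,c,,,,,,,,TRUE
B4e,B4,e,,,,,,,,TRUE
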