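patient_id,conditions,ferritin_ugL,published_hscore,published_band,clinician_hlh_diagnosis
P01,ESRD; AKI; ALI; renal transplant,9107,174,54,FALSE
P02,Lung transplant; sepsis,>16500,174,54,FALSE
P03,CLL; CMV,5150,177,54,FALSE
P04,HLH; Sweet's syndrome,>16500,177,54,TRUE
P05,Massive haemorrhage; DIC,>16500,181,70,FALSE
P06,Myeloma,14349,193,80,FALSE
P07,HLH; ALL,>16500,194,80,TRUE
P08,ALL; sepsis,>16500,202,88,FALSE
P09,AML; GVHD,>16500,205,88,FALSE
P10,HLH; SLE; HSV,12273,227,96,TRUE
P11,APML; multi-organ failure,>16500,241,99,FALSE
P12,HLH; bilateral lung transplant,>16500,267,>99,TRUE
P13,HLH; SLE; CMV,>16500,291,>99,TRUE
P14,HLH; EBV,>16500,321,>99,TRUE
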