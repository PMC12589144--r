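feature,label,test,value_neg,value_pos,n_neg,n_pos,printed_statistic,printed_p
mean_ferritin,Mean peak serum ferritin level (ug/L),mann-whitney,9260,14706,106,14,-3.95719,0.00008
haemoglobin_low,Patients with haemoglobin < 90 g/L,chi-squared,38,12,106,14,12.6515,0.000375
platelets_low,Patients with platelets < 100e9/L,chi-squared,44,12,106,14,9.7093,0.001833
neutrophils_low,Patients with neutrophils < 1e9/L,chi-squared,12,8,106,14,18.6954,0.000015
fever,Patients with a fever,chi-squared,37,12,106,14,13.214,0.000278
hepatomegaly,Patients with hepatomegaly,chi-squared,11,7,106,14,15.2275,0.000095
splenomegaly,Patients with splenomegaly,chi-squared,18,10,106,14,20.4939,0.00001
triglycerides_high,Patients with triglycerides > 1.5 mmol/L,chi-squared,6,10,106,14,46.2907,0.00001
fibrinogen_low,Patients with fibrinogen < 2.5 g/L,chi-squared,10,7,106,14,16.7361,0.000043
haemophagocytosis,Patients with haemophagocytosis recorded,chi-squared,1,3,106,14,16.1056,0.00006
immunosuppression,Patients with immunosuppression,chi-squared,31,12,106,14,17.1505,0.000035
transaminase_deranged,Patients with transaminase derangement (AST > 30 / ALT > 100),chi-squared,47,10,106,14,3.639,0.05644
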