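drug,dose_mg_d,scenario,sbp,dbp,MAP,PP,HR,CO,SV,EF,SW,cii,provenance
enalapril,20,baseline,155,101,119,54,73,5.26,72,28.35,2.95,9.85,"trial measurement (SBP/DBP); remaining components model-estimated"
enalapril,20,simulated,143,92,109,51,73,5.48,75,32.05,2.70,4.01,"model simulation of 20 mg/d response"
enalapril,20,measured,137,88,NA,NA,NA,NA,NA,NA,NA,NA,"trial measurement after 20 mg/d"
lisinopril,20,baseline,158,94,115,64,73,5.11,70,27.24,3.03,13.22,"trial measurement (SBP/DBP); remaining components model-estimated"
lisinopril,20,simulated,141,90,107,51,73,5.62,77,34.53,2.48,1.80,"model simulation of 20 mg/d response"
lisinopril,20,measured,140,88,NA,NA,NA,NA,NA,NA,NA,NA,"trial measurement after 20 mg/d"
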