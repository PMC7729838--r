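characteristic,level,n,pct
total,total,1510,100
age_band,65-74,1124,74.4
age_band,75-84,329,21.8
age_band,85+,57,3.8
gender,male,909,60.2
gender,female,601,39.8
nationality,Han,1416,93.8
nationality,Korean,68,4.5
nationality,Other,25,1.7
occupation,Farmers,246,16.3
occupation,Retired,337,22.3
occupation,Unemployed,84,5.6
occupation,Workers,55,3.6
occupation,Staff,23,1.5
occupation,Other,33,2.2
occupation,Unspecified,732,48.5
marital_status,Unmarried,9,0.6
marital_status,Married,1375,91.0
marital_status,Death of a spouse,59,3.8
marital_status,Divorce,11,0.7
marital_status,Other,56,3.7
n_comorbidities,0,339,22.5
n_comorbidities,1,230,15.2
n_comorbidities,2,262,17.3
n_comorbidities,3,203,13.5
n_comorbidities,>3,496,31.5
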