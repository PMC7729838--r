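category,icd10_code,n_cases,single_pct,multiple_pct
Pneumonia,J18,299,11.7,88.3
Cerebral infarction,I63,230,10.9,89.1
Hypertension,I10,202,8.4,91.6
Pleural conditions,J94,174,11.5,88.5
Heart failure,I50,112,0.0,100.0
Atherosclerotic heart disease,I25.1,102,3.9,96.1
Disorders of glycoprotein metabolism,E77,98,1.0,99.0
Type 2 diabetes mellitus,E11,93,10.8,89.2
Emphysema,J43,90,4.4,95.6
Cardiac arrhythmias,I49,70,1.4,98.6
Chronic ischemic heart disease,I25,69,0.0,100.0
Pericardium diseases,I31,65,10.8,89.2
Cyst of kidney,N28.1,65,1.5,98.5
Pulmonary collapse,J98.1,62,4.8,95.2
Anemia,D64,59,3.4,96.6
Respiratory failure,J96,51,7.8,92.2
Hypokalemia,E87.6,42,0.0,100.0
Chronic obstructive pulmonary disease,J44,41,7.3,92.7
Cholelithiasis,K80,41,2.4,97.6
Hyponatremia,E87.1,36,5.6,94.4
Fatty liver,K76.0,30,0.0,100.0
Thyroid nodule,E04.1,29,3.4,96.6
Angina pectoris,I20,29,0.0,100.0
Ischemic cardiomyopathy,I25.5,28,3.6,96.4
Hyperplasia of the prostate,N40,28,3.6,96.4
Disorders of calcium metabolism,E83.5,27,0.0,100.0
Atrial fibrillation and flutter,I48,27,3.7,96.3
Degenerative diseases of the nervous system,G31,24,0.0,100.0
Interstitial pulmonary diseases,J84,22,13.6,86.4
Chronic sinusitis,J32,21,4.8,95.2
Calculus of the kidney,N20.0,21,0.0,100.0
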