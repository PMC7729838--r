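rule_no,lhs,rhs,support,confidence,lift
1,Degenerative diseases of the nervous system,Cerebral infarction,0.02,0.71,2.60
2,Disorders of calcium metabolism,Disorders of glycoprotein metabolism,0.02,0.56,4.78
3,Ischemic cardiomyopathy,Heart failure,0.02,0.61,4.58
4,Angina pectoris,Atherosclerotic heart disease,0.02,0.55,4.57
5,Angina pectoris,Heart failure,0.02,0.69,5.20
6,Anemia,Disorders of glycoprotein metabolism,0.04,0.53,4.53
7,Chronic ischemic heart disease,Heart failure,0.05,0.62,4.70
8,Atherosclerotic heart disease,Heart failure,0.06,0.51,3.84
9,Atherosclerotic heart disease|Ischemic cardiomyopathy,Heart failure,0.01,0.92,6.96
10,Ischemic cardiomyopathy|Heart failure,Atherosclerotic heart disease,0.01,0.71,5.84
11,Ischemic cardiomyopathy|Heart failure,Hypertension,0.01,0.59,2.46
12,Hypertension|Ischemic cardiomyopathy,Heart failure,0.01,0.83,6.28
13,Anemia|Hyponatremia,Disorders of glycoprotein metabolism,0.01,0.60,5.17
14,Disorders of glycoprotein metabolism|Hyponatremia,Anemia,0.01,0.60,8.58
15,Angina pectoris|Chronic ischemic heart disease,Pneumonia,0.01,0.90,2.54
16,Angina pectoris|Pneumonia,Chronic ischemic heart disease,0.01,0.53,6.48
17,Angina pectoris|Atherosclerotic heart disease,Heart failure,0.01,0.69,5.18
18,Angina pectoris|Heart failure,Atherosclerotic heart disease,0.01,0.55,4.55
19,Hypertension|Angina pectoris,Heart failure,0.01,0.82,6.17
20,Angina pectoris|Pneumonia,Heart failure,0.01,0.65,4.88
21,Anemia|Hypokalemia,Disorders of glycoprotein metabolism,0.01,0.69,5.92
22,Disorders of glycoprotein metabolism|Hypokalemia,Anemia,0.01,0.58,8.28
23,Hypokalemia|Pleural conditions,Disorders of glycoprotein metabolism,0.01,0.64,5.54
24,Anemia|Pleural conditions,Disorders of glycoprotein metabolism,0.01,0.56,4.84
25,Pericardium diseases|Pneumonia,Pleural conditions,0.02,0.52,2.51
26,Atherosclerotic heart disease|Cardiac arrhythmias,Heart failure,0.02,0.67,5.02
27,Cardiac arrhythmias|Heart failure,Atherosclerotic heart disease,0.02,0.58,4.83
28,Type 2 diabetes mellitus|Chronic ischemic heart disease,Heart failure,0.01,0.73,5.53
29,Type 2 diabetes mellitus|Heart failure,Chronic ischemic heart disease,0.01,0.52,6.41
30,Chronic ischemic heart disease|Pleural conditions,Heart failure,0.01,0.59,4.43
31,Hypertension|Chronic ischemic heart disease,Heart failure,0.02,0.67,5.02
32,Chronic ischemic heart disease|Cerebral infarction,Heart failure,0.01,0.50,3.77
33,Chronic ischemic heart disease|Pneumonia,Heart failure,0.02,0.53,4.00
34,Heart failure|Pneumonia,Chronic ischemic heart disease,0.02,0.55,6.71
35,Type 2 diabetes mellitus|Atherosclerotic heart disease,Heart failure,0.01,0.53,3.99
36,Type 2 diabetes mellitus|Heart failure,Hypertension,0.02,0.62,2.59
37,Atherosclerotic heart disease|Pleural conditions,Heart failure,0.02,0.59,4.45
38,Hypertension|Atherosclerotic heart disease,Heart failure,0.03,0.67,5.02
39,Hypertension|Heart failure,Atherosclerotic heart disease,0.03,0.50,4.14
40,Atherosclerotic heart disease|Cerebral infarction,Heart failure,0.02,0.50,3.77
41,Heart failure|Cerebral infarction,Atherosclerotic heart disease,0.02,0.58,4.77
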