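pt_name	smq_code	algorithm
atrial fibrillation	20000049	narrow
ventricular tachycardia	20000049	narrow
cardiac failure	20000004	narrow
ejection fraction decreased	20000004	narrow
cardiomyopathy	20000150	narrow
cardiac dysfunction	20000150	narrow
pulmonary embolism	20000081	narrow
deep vein thrombosis	20000081	narrow
hypertension	20000147	narrow
blood pressure increased	20000147	narrow
myocardial infarction	20000043	narrow
angina pectoris	20000043	narrow
pulmonary hypertension	20000130	narrow
pulmonary arterial hypertension	20000130	narrow
electrocardiogram qt prolonged	20000001	narrow
torsade de pointes	20000001	narrow
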