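disease,weight
hypertension,1.2
dyslipidemia,0.9
diabetes,1.6
cancer,3.1
chronic_lung_disease,1.8
liver_disease,1.4
heart_disease,2.2
stroke,2.7
kidney_disease,1.5
digestive_disease,0.8
emotional_problem,1.1
memory_related_disease,2.4
arthritis,1.0
asthma,1.3
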