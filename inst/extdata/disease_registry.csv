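disease,source,sex_restriction,age_cutoff
Anxiety and mood disorders,chronic-disease-registry,none,1
Asthma,chronic-disease-registry,none,1
Chronic kidney disease,chronic-disease-registry,none,1
Diabetes mellitus,chronic-disease-registry,none,1
Epilepsy,chronic-disease-registry,none,1
Heart failure,chronic-disease-registry,none,1
Osteoarthritis,chronic-disease-registry,none,1
Rheumatoid arthritis,chronic-disease-registry,none,1
Schizophrenia and delusional disorders,chronic-disease-registry,none,10
Gout,chronic-disease-registry,none,20
Hypertension,chronic-disease-registry,none,20
Ischemic heart disease,chronic-disease-registry,none,20
Multiple sclerosis,chronic-disease-registry,none,20
Stroke,chronic-disease-registry,none,20
COPD,chronic-disease-registry,none,35
Alzheimers and other dementias,chronic-disease-registry,none,40
Parkinsons disease,chronic-disease-registry,none,40
Osteoporosis,chronic-disease-registry,none,50
Breast cancer,cancer-registry,female-only,NA
Colorectal cancer,cancer-registry,none,NA
Hematological cancer,cancer-registry,none,NA
Lung cancer,cancer-registry,none,NA
Melanoma,cancer-registry,none,NA
Other solid organ cancer,cancer-registry,none,NA
Prostate cancer,cancer-registry,male-only,NA
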