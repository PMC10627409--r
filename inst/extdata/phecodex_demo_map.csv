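icd_code,vocabulary,phecode,phecode_string,category,icd10_only
K40.1,ICD10CM,GI_520.11,Inguinal hernia,Gastrointestinal,false
K40.1,ICD10CM,ID_091,Gangrene,Infectious Diseases,false
550.0,ICD9CM,GI_520.11,Inguinal hernia,Gastrointestinal,false
550.0,ICD9CM,ID_091,Gangrene,Infectious Diseases,false
K40.9,ICD10CM,GI_520.11,Inguinal hernia,Gastrointestinal,false
K46.9,ICD10CM,GI_520.1,Abdominal hernia,Gastrointestinal,false
553.9,ICD9CM,GI_520.1,Abdominal hernia,Gastrointestinal,false
K46,ICD10WHO,GI_520,Hernia,Gastrointestinal,false
550.9,ICD9CM,GI_520,Hernia,Gastrointestinal,false
785.4,ICD9CM,ID_091,Gangrene,Infectious Diseases,false
J15.2,ICD10CM,ID_009,Staphylococcus infections,Infectious Diseases,false
J15.2,ICD10CM,RE_468.2,Bacterial pneumonia,Respiratory,false
482.4,ICD9CM,ID_009,Staphylococcus infections,Infectious Diseases,false
482.4,ICD9CM,RE_468.2,Bacterial pneumonia,Respiratory,false
041.10,ICD9CM,ID_009,Staphylococcus infections,Infectious Diseases,false
J18.9,ICD10CM,RE_468,Pneumonia,Respiratory,false
486,ICD9CM,RE_468,Pneumonia,Respiratory,false
I49.9,ICD10CM,CV_416,Cardiac arrhythmias,Cardiovascular,false
427.9,ICD9CM,CV_416,Cardiac arrhythmias,Cardiovascular,false
I48.91,ICD10CM,CV_416.2,Atrial fibrillation and flutter,Cardiovascular,false
427.3,ICD9CM,CV_416.2,Atrial fibrillation and flutter,Cardiovascular,false
I48.0,ICD10CM,CV_416.21,Atrial fibrillation,Cardiovascular,false
427.31,ICD9CM,CV_416.21,Atrial fibrillation,Cardiovascular,false
I48.92,ICD10CM,CV_416.22,Atrial flutter,Cardiovascular,false
427.32,ICD9CM,CV_416.22,Atrial flutter,Cardiovascular,false
I48.3,ICD10CM,CV_416.221,Typical atrial flutter*,Cardiovascular,true
I48.4,ICD10CM,CV_416.222,Atypical atrial flutter*,Cardiovascular,true
E13.9,ICD10CM,EM_202,Diabetes mellitus,Endocrine/Metabolic,false
250.00,ICD9CM,EM_202,Diabetes mellitus,Endocrine/Metabolic,false
E10.9,ICD10CM,EM_202.1,Type 1 diabetes,Endocrine/Metabolic,false
250.01,ICD9CM,EM_202.1,Type 1 diabetes,Endocrine/Metabolic,false
O24.01,ICD10CM,EM_202.1,Type 1 diabetes,Endocrine/Metabolic,false
O24.01,ICD10CM,PG_010,Diabetes in pregnancy,Pregnancy,false
O24.9,ICD10CM,PG_010,Diabetes in pregnancy,Pregnancy,false
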