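icd_code,vocabulary,phecode,phecode_string,category,exclude_range
410.90,ICD9CM,410,Myocardial infarction,circulatory system,410-414.99
I21.9,ICD10CM,410,Myocardial infarction,circulatory system,410-414.99
411.1,ICD9CM,411,Ischemic heart disease,circulatory system,410-414.99
I20.0,ICD10CM,411,Ischemic heart disease,circulatory system,410-414.99
414.8,ICD9CM,414,Other chronic ischemic heart disease,circulatory system,410-414.99
427.9,ICD9CM,427,Cardiac dysrhythmias,circulatory system,427-427.99
427.31,ICD9CM,427.2,Atrial fibrillation and flutter,circulatory system,427-427.99
I48.91,ICD10CM,427.2,Atrial fibrillation and flutter,circulatory system,427-427.99
428.0,ICD9CM,428,Congestive heart failure,circulatory system,428-428.99
250.00,ICD9CM,250,Diabetes mellitus,endocrine/metabolic,249-250.99
250.01,ICD9CM,250.1,Type 1 diabetes,endocrine/metabolic,249-250.99
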