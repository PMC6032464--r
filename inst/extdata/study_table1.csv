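patient_id,sex,age_years,segment,size_mm,outcome_3d,outcome_10d,outcome_final,interval_premri_tace_days,interval_tace_followup_days,followup_modality
1,f,79,8,56,PR,PR,SD,1,74,CTHA
1,f,79,8,21,SD,SD,SD,1,74,CTHA
2,m,75,6,14,CR,CR,CR,8,73,CT
2,m,75,3,9,SD,CR,CR,8,73,CT
3,m,66,4,10,SD,SD,SD,1,40,CT
3,m,66,3,20,CR,CR,PR,1,40,CT
4,m,73,7,11,CR,CR,SD,1,114,CT
4,m,73,3,10,CR,CR,SD,1,114,CT
5,f,69,7,7,CR,CR,SD,1,87,CT
5,f,69,5,8,CR,CR,SD,1,87,CT
6,m,60,8,80,PR,PR,PD,3,51,MRI
7,f,56,4,15,CR,CR,CR,1,72,CT
7,f,56,1,16,CR,CR,CR,1,72,CT
8,m,68,7,44,PR,PR,PR,4,68,CT
8,m,68,3,11,CR,CR,SD,4,68,CT
9,m,71,7,11,CR,CR,PD,4,58,CT
9,m,71,3,31,CR,CR,SD,4,58,CT
10,m,42,4,18,SD,SD,SD,3,71,CT
10,m,42,3,17,SD,SD,SD,3,71,CT
11,m,56,6,36,PR,PR,PR,3,71,CTHA
11,m,56,1,29,CR,CR,CR,3,71,CTHA
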