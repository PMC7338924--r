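taxonomy,category,keyword,ambiguous_flag,context_list
health,Respiratory,cough,0,
health,Respiratory,wheezing,0,
health,Respiratory,asthma,0,
health,Respiratory,shortness of breath,0,
health,Respiratory,phlegm,0,
health,Cardiovascular,chest pain,0,
health,Cardiovascular,heart palpitations,0,
health,Cardiovascular,high blood pressure,0,
health,Cardiovascular,rapid heartbeat,0,
health,Neurological,headache,0,
health,Neurological,dizziness,0,
health,Neurological,migraine,0,
health,Neurological,seizure,0,
health,Psychological,anxiety,0,
health,Psychological,depression,0,
health,Psychological,panic attack,0,
health,Psychological,insomnia,0,
health,Digestive,nausea,0,
health,Digestive,stomach ache,0,
health,Digestive,vomiting,0,
health,Digestive,diarrhea,0,
health,Mouth,dry mouth,0,
health,Mouth,mouth sores,0,
health,Mouth,gum pain,0,
health,Mouth,bad breath,0,
health,Throat,sore throat,0,
health,Throat,throat irritation,0,
health,Throat,scratchy throat,0,
health,Throat,throat hit,0,
health,Cancer,cancer,0,
health,Cancer,tumor,0,
health,Cancer,carcinoma,0,
health,Cancer,lung cancer,0,
health,Other,fatigue,0,
health,Other,rash,0,
health,Other,itching,0,
health,Other,swelling,0,
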