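factor_id,label,level,rule_kind,lookback,count_threshold,source_domain,code,count_unit,code_group
c_homeless,Presents with problem of being homeless,consultation,code_match,,,events,13F6.,,13F6.
c_safeguarding,Child protection or adult safeguarding concerns raised,consultation,code_match,,,events,13VE.,,13VE.
c_safeguarding,Child protection or adult safeguarding concerns raised,consultation,code_match,,,events,13Vj.,,13Vj.
c_domestic_violence,Concerns about domestic violence raised,consultation,code_match,,,events,14X1.,,14X1.
c_domestic_violence,Concerns about domestic violence raised,consultation,code_match,,,events,14XD.,,14XD.
c_learning_disability,About learning disability/autism,consultation,code_match,,,events,E30..,,E30..
c_learning_disability,About learning disability/autism,consultation,code_match,,,events,Eu81.,,Eu81.
c_end_of_life,Discussion about end-of-life issues,consultation,code_match,,,events,8CM1.,,8CM1.
c_end_of_life,Discussion about end-of-life issues,consultation,code_match,,,events,1Z01.,,1Z01.
c_mental_health,About mental health problems,consultation,code_match,,,events,E20..,,E20..
c_mental_health,About mental health problems,consultation,code_match,,,events,E21..,,E21..
c_mental_health,About mental health problems,consultation,code_match,,,events,Eu4..,,Eu4..
c_multi_diagnoses,>=2 diagnoses from unique chapters recorded,consultation,count_rule,,2,events,C2...,chapters,C2...
c_multi_diagnoses,>=2 diagnoses from unique chapters recorded,consultation,count_rule,,2,events,D10..,chapters,D10..
c_multi_diagnoses,>=2 diagnoses from unique chapters recorded,consultation,count_rule,,2,events,F26..,chapters,F26..
c_multi_diagnoses,>=2 diagnoses from unique chapters recorded,consultation,count_rule,,2,events,G30..,chapters,G30..
c_multi_diagnoses,>=2 diagnoses from unique chapters recorded,consultation,count_rule,,2,events,H06..,chapters,H06..
c_multi_diagnoses,>=2 diagnoses from unique chapters recorded,consultation,count_rule,,2,events,J57..,chapters,J57..
c_multi_diagnoses,>=2 diagnoses from unique chapters recorded,consultation,count_rule,,2,events,K19..,chapters,K19..
c_dementia,About dementia,consultation,code_match,,,events,E00..,,E00..
c_dementia,About dementia,consultation,code_match,,,events,Eu02.,,Eu02.
c_drug_alcohol,About problematic drug or alcohol use,consultation,code_match,,,events,E23..,,E23..
c_drug_alcohol,About problematic drug or alcohol use,consultation,code_match,,,events,E24..,,E24..
c_preventive_tasks,>=2 preventive/routine tasks carried out,consultation,count_rule,,2,events,6871.,codes,6871.
c_preventive_tasks,>=2 preventive/routine tasks carried out,consultation,count_rule,,2,events,6872.,codes,6872.
c_preventive_tasks,>=2 preventive/routine tasks carried out,consultation,count_rule,,2,events,9OX1.,codes,9OX1.
c_preventive_tasks,>=2 preventive/routine tasks carried out,consultation,count_rule,,2,events,9OX2.,codes,9OX2.
c_preventive_tasks,>=2 preventive/routine tasks carried out,consultation,count_rule,,2,events,65E..,codes,65E..
c_many_drugs,>=3 unique substances prescribed,consultation,count_rule,,3,prescriptions,-,substances,-
c_first_cancer,First consultation after cancer diagnosis,consultation,first_consult_after_dx,,,events,B22..,,B22..
c_first_cancer,First consultation after cancer diagnosis,consultation,first_consult_after_dx,,,events,B34..,,B34..
c_first_diabetes,First consultation after diabetes diagnosis,consultation,first_consult_after_dx,,,events,C10..,,C10..
c_first_diabetes,First consultation after diabetes diagnosis,consultation,first_consult_after_dx,,,events,C109.,,C109.
c_mus,Medically unexplained symptoms raised,consultation,code_match,,,events,1B1A.,,1B1A.
c_emergency_admission,Results in emergency hospital admission,consultation,code_match,,,events,8H2..,,8H2..
c_emergency_admission,Results in emergency hospital admission,consultation,code_match,,,events,8H21.,,8H21.
c_urgent_secondary,Results in urgent secondary care assessment,consultation,code_match,,,events,8H26.,,8H26.
c_urgent_secondary,Results in urgent secondary care assessment,consultation,code_match,,,events,8H27.,,8H27.
c_chronic_pain,About chronic pain management,consultation,code_match,,,events,N14y.,,N14y.
c_chronic_pain,About chronic pain management,consultation,code_match,,,events,R021.,,R021.
p_homelessness,Homelessness in previous year,patient,code_match,365,,events,13F6.,,13F6.
p_safeguarding,Child protection/safeguarding in previous 3 years,patient,code_match,1095,,events,13VE.,,13VE.
p_safeguarding,Child protection/safeguarding in previous 3 years,patient,code_match,1095,,events,13Vj.,,13Vj.
p_domestic_violence,Domestic violence in previous year,patient,code_match,365,,events,14X1.,,14X1.
p_domestic_violence,Domestic violence in previous year,patient,code_match,365,,events,14XD.,,14XD.
p_no_english,Interpreter needed/no English in last 3 years,patient,code_match,1095,,events,13l0.,,13l0.
p_no_english,Interpreter needed/no English in last 3 years,patient,code_match,1095,,events,9NU..,,9NU..
p_learning_disability,Learning disability/autism ever,patient,code_match,ever,,events,E30..,,E30..
p_learning_disability,Learning disability/autism ever,patient,code_match,ever,,events,Eu81.,,Eu81.
p_dementia,Dementia ever,patient,code_match,ever,,events,E00..,,E00..
p_dementia,Dementia ever,patient,code_match,ever,,events,Eu02.,,Eu02.
p_palliative,Receiving palliative care ever,patient,code_match,ever,,events,8CM1.,,8CM1.
p_palliative,Receiving palliative care ever,patient,code_match,ever,,events,1Z01.,,1Z01.
p_drug_alcohol,Drug misuse/alcoholism in previous year,patient,code_match,365,,events,E23..,,E23..
p_drug_alcohol,Drug misuse/alcoholism in previous year,patient,code_match,365,,events,E24..,,E24..
p_severe_mental_illness,Severe mental illness in previous 3 years,patient,code_match,1095,,events,Eu2..,,Eu2..
p_severe_mental_illness,Severe mental illness in previous 3 years,patient,code_match,1095,,events,E10..,,E10..
p_multimorbidity,>=3 major long-term conditions,patient,count_rule,ever,3,events,C11..,groups,diabetes
p_multimorbidity,>=3 major long-term conditions,patient,count_rule,ever,3,events,G33..,groups,chd
p_multimorbidity,>=3 major long-term conditions,patient,count_rule,ever,3,events,H37..,groups,copd
p_multimorbidity,>=3 major long-term conditions,patient,count_rule,ever,3,events,Eu32.,groups,depression
p_multimorbidity,>=3 major long-term conditions,patient,count_rule,ever,3,events,N05..,groups,arthritis
p_multimorbidity,>=3 major long-term conditions,patient,count_rule,ever,3,events,F51..,groups,migraine
p_paraplegia,Paraplegia ever,patient,code_match,ever,,events,F229.,,F229.
p_housebound,Housebound or nursing home in previous 3 years,patient,code_match,1095,,events,13CA.,,13CA.
p_housebound,Housebound or nursing home in previous 3 years,patient,code_match,1095,,events,13F71,,13F71
p_personality_disorder,Personality/disruptive disorder ever,patient,code_match,ever,,events,Eu34.,,Eu34.
p_personality_disorder,Personality/disruptive disorder ever,patient,code_match,ever,,events,E21z.,,E21z.
p_mus_year,Medically unexplained symptoms in last year,patient,code_match,365,,events,1B1A.,,1B1A.
p_frequent_attender,Frequent attender (>=14 consultations in last year),patient,count_rule,365,14,consultations,-,consultations,-
p_chronic_pain,Chronic pain in previous year,patient,code_match,365,,events,N14y.,,N14y.
p_chronic_pain,Chronic pain in previous year,patient,code_match,365,,events,R021.,,R021.
p_polypharmacy,Polypharmacy (>=9 unique substances in previous 3 months),patient,count_rule,91,9,prescriptions,-,substances,-
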