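column,type,values,description
subject_id,character,unique per subject,opaque subject identifier
timepoint,character,"W2, M3, M6, M12",assessment timepoint (2 weeks; 3; 6; 12 months post-injury)
gcs,integer,3-15,Glasgow Coma Scale at emergency-department arrival
headache,integer,0-4 raw / 0-3 recoded,RPQ item 1
dizziness,integer,0-4 raw / 0-3 recoded,RPQ item 2
nausea,integer,0-4 raw / 0-3 recoded,RPQ item 3
noise_sensitivity,integer,0-4 raw / 0-3 recoded,RPQ item 4
sleep_disturbance,integer,0-4 raw / 0-3 recoded,RPQ item 5
fatigue,integer,0-4 raw / 0-3 recoded,RPQ item 6
irritable,integer,0-4 raw / 0-3 recoded,RPQ item 7
depressed,integer,0-4 raw / 0-3 recoded,RPQ item 8
frustrated,integer,0-4 raw / 0-3 recoded,RPQ item 9
poor_memory,integer,0-4 raw / 0-3 recoded,RPQ item 10
poor_concentration,integer,0-4 raw / 0-3 recoded,RPQ item 11
slow_thinking,integer,0-4 raw / 0-3 recoded,RPQ item 12
blurred_vision,integer,0-4 raw / 0-3 recoded,RPQ item 13
light_sensitivity,integer,0-4 raw / 0-3 recoded,RPQ item 14
double_vision,integer,0-4 raw / 0-3 recoded,RPQ item 15
restlessness,integer,0-4 raw / 0-3 recoded,RPQ item 16
age,numeric,years,age at injury
female_sex,integer,0/1,1 = female
education,numeric,years,years of education
prior_tbi,integer,0/1,previous traumatic brain injury
psychiatric_history,integer,0/1,psychiatric history at baseline
ct_positive,integer,0/1,positive head CT finding
gose,integer,1-8 or empty,Glasgow Outcome Scale Extended (8 = complete recovery)
qolibri,numeric,0-100 or empty,QOLIBRI-OS overall quality-of-life score
sf12_pcs,numeric,continuous or empty,SF-12 physical component summary
sf12_mcs,numeric,continuous or empty,SF-12 mental component summary
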