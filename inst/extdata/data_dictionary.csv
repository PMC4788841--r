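table,column,type,description
observations,patient_id,character,Opaque patient identifier (one per unique patient)
observations,sex,character,"Patient sex, female or male"
observations,birth_date,date,Date of birth (generalized tables may hold year-month / year / 5-year band)
observations,postal_code,character,6-character Canadian postal code; may be generalized or missing
observations,height,numeric,Height in metres; NA when not measured at the visit
observations,weight,numeric,Weight in kilograms; NA when not measured at the visit
observations,observation_date,date,Visit date
observations,diabetes,integer,Chronic-disease flag (0/1)
observations,hypertension,integer,Chronic-disease flag (0/1)
observations,osteoarthritis,integer,Chronic-disease flag (0/1)
observations,depression,integer,Chronic-disease flag (0/1)
observations,copd,integer,Chronic-disease flag (0/1)
observations,dementia,integer,Chronic-disease flag (0/1)
observations,parkinsons,integer,Chronic-disease flag (0/1)
observations,epilepsy,integer,Chronic-disease flag (0/1)
observations,note,character,Free-text visit note; may contain direct identifiers before scrubbing
observations,pregnancy_edb,date,Estimated date of birth of the infant for pregnancy episodes; NA otherwise
conversion,postal_code,character,6-character postal code
conversion,area_id,character,Census dissemination-area identifier the code maps to
conversion,urban,logical,TRUE for urban areas (postal code second character non-zero)
conversion,in_region,logical,TRUE when the area lies inside the study region boundary
deprivation,area_id,character,Census dissemination-area identifier
deprivation,material_score,numeric,"Material deprivation score (education, employment, income); higher = more deprived"
deprivation,social_score,numeric,"Social deprivation score (marital status, family structure); higher = more deprived"
deprivation,combined_score,numeric,Combined material and social deprivation score
deprivation,in_region,logical,TRUE when the area lies inside the study region boundary
deprivation,urban,logical,TRUE for urban areas
truth,patient_id,character,Opaque patient identifier
truth,true_obese,logical,Planted obesity status drawn from the quintile prevalence gradient
truth,true_bmi,numeric,Planted base BMI in kg/m2 (visit measures add noise)
truth,true_quintile,integer,Planted combined-deprivation quintile of the patient's area (1 least deprived)
truth,true_area_id,character,Dissemination area the patient was assigned before postal-code defects
truth,measure_defect,character,"Injected measurement defect: none, pregnancy, missing_height, missing_weight, outlier"
truth,postal_defect,character,"Injected postal defect: none, out_of_region, erroneous, missing, unmatched"
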