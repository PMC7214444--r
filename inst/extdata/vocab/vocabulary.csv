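concept_id,domain,label
C_DM,condition,Diabetes mellitus
C_T1DM,condition,Type 1 diabetes mellitus
C_T2DM,condition,Type 2 diabetes mellitus
C_DIABETIC_NEPHROPATHY,condition,Diabetic nephropathy
C_KIDNEY_DISEASE,condition,Renal disease
C_RETINOPATHY,condition,Diabetic retinopathy
C_NEUROPATHY,condition,Diabetic neuropathy
C_ACS,condition,Acute coronary syndrome
C_UA,condition,Unstable angina
C_NSTEMI,condition,Myocardial infarction without ST elevation
C_STEMI,condition,Myocardial infarction with ST elevation
C_MI,condition,Myocardial infarction
C_HTN,condition,Hypertension
C_SYS_HTN,condition,Systolic hypertension
C_ANGINA,condition,Angina pectoris
C_STROKE,condition,Stroke
C_PAD,condition,Peripheral artery disease
C_LIPID_DISORDER,condition,Lipid disorder
C_SMOKING,condition,Current smoker
C_AFIB,condition,Atrial fibrillation
C_LVH,condition,Left ventricular hypertrophy
P_REVASC,procedure,Coronary revascularization
P_PCI,procedure,Percutaneous coronary intervention
P_CABG,procedure,Coronary artery bypass grafting
P_AMPUTATION,procedure,Amputation of lower limb
D_LIPID_LOWERING,drug,Lipid lowering agent
D_STATIN,drug,HMG-CoA reductase inhibitor
D_ATORVA,drug,Atorvastatin
D_PRAVA,drug,Pravastatin
D_DPP4,drug,DPP-4 inhibitor
D_SITA,drug,Sitagliptin
D_SULFONYLUREA,drug,Sulfonylurea
D_GLIM,drug,Glimepiride
D_AHT,drug,Antihypertensive agent
D_ACEI,drug,ACE inhibitor
D_BENAZEPRIL,drug,Benazepril
D_ARB,drug,Angiotensin receptor blocker
D_LOSARTAN,drug,Losartan
D_CCB,drug,Calcium channel blocker
D_AMLODIPINE,drug,Amlodipine
D_THIAZIDE,drug,Thiazide diuretic
D_HCTZ,drug,Hydrochlorothiazide
D_BBLOCK,drug,Beta blocker
D_ANTIPLATELET,drug,Antiplatelet agent
M_HBA1C,measurement,Hemoglobin A1c (%)
M_FPG,measurement,Fasting plasma glucose (mg/dL)
M_GLUCOSE,measurement,Serum glucose (mg/dL)
M_BMI,measurement,Body mass index (kg/m2)
M_WEIGHT,measurement,Body weight (kg)
M_WAIST,measurement,Waist circumference (cm)
M_SBP,measurement,Systolic blood pressure (mmHg)
M_DBP,measurement,Diastolic blood pressure (mmHg)
M_MAP,measurement,Mean arterial pressure (mmHg)
M_PULSE,measurement,Pulse (bpm)
M_CREATININE,measurement,Serum creatinine (mg/dL)
M_EGFR,measurement,Estimated glomerular filtration rate (mL/min/1.73m2)
M_TC,measurement,Total cholesterol (mg/dL)
M_LDL,measurement,LDL cholesterol (mg/dL)
M_HDL,measurement,HDL cholesterol (mg/dL)
M_TG,measurement,Triglycerides (mg/dL)
M_HEMOGLOBIN,measurement,Hemoglobin (g/dL)
M_ALBCREAT,measurement,Urinary albumin:creatinine ratio (mg/g)
M_DM_DURATION,measurement,Years since diabetes diagnosis (years)
M_POTASSIUM,measurement,Serum potassium (mmol/L)
G_MALE,demographic,Male
G_FEMALE,demographic,Female
G_UNKNOWN,demographic,Gender unknown
R_WHITE,demographic,White
R_BLACK,demographic,Black or African American
R_ASIAN,demographic,Asian
R_MULTI,demographic,Multi-racial
R_NATIVE,demographic,Native American or Alaska Native
R_PACIFIC,demographic,Native Hawaiian or Pacific Islander
R_HISPANIC,demographic,Hispanic
R_OTHER,demographic,Other race
R_UNKNOWN,demographic,Race unknown
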