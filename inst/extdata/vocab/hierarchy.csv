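parent_id,child_id
C_DM,C_T1DM
C_DM,C_T2DM
C_DM,C_DIABETIC_NEPHROPATHY
C_DM,C_RETINOPATHY
C_DM,C_NEUROPATHY
C_KIDNEY_DISEASE,C_DIABETIC_NEPHROPATHY
C_ACS,C_UA
C_ACS,C_NSTEMI
C_ACS,C_STEMI
C_MI,C_NSTEMI
C_MI,C_STEMI
C_ANGINA,C_UA
C_HTN,C_SYS_HTN
P_REVASC,P_PCI
P_REVASC,P_CABG
D_LIPID_LOWERING,D_STATIN
D_STATIN,D_ATORVA
D_STATIN,D_PRAVA
D_DPP4,D_SITA
D_SULFONYLUREA,D_GLIM
D_AHT,D_ACEI
D_AHT,D_ARB
D_AHT,D_CCB
D_AHT,D_THIAZIDE
D_AHT,D_BBLOCK
D_ACEI,D_BENAZEPRIL
D_ARB,D_LOSARTAN
D_CCB,D_AMLODIPINE
D_THIAZIDE,D_HCTZ
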