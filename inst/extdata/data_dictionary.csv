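table,column,description,unit
observations,patient_id,Synthetic patient identifier (P001 ...),
observations,time_day,Days since CAR T-cell infusion (0 = infusion day),day
observations,observable,"One of: E_blood, C_blood, B_blood, spd, endo_prop_naive/cm/em/eff, car_prop_naive/cm/em/eff",
observations,value,Observed value; counts are per 5.3 L of blood (average adult blood volume),see unit column
observations,unit,"cells_per_5.3L for blood counts, cm2 for spd, proportion for phenotype fractions",
lesions,patient_id,Synthetic patient identifier,
lesions,lesion_id,Lesion index (the default generator emits one lesion),
lesions,baseline_d,Longest lesion diameter at the first imaging visit,cm
lesions,final_d,Longest lesion diameter at the last imaging visit,cm
covariates,patient_id,Synthetic patient identifier,
covariates,time_day,Days since infusion,day
covariates,covariate,"One of: LDH, IL7, IL15",
covariates,value,"LDH in arbitrary units (affine in lesion volume); cytokines normalized to [0, 1]",
truth,patient_id,Synthetic patient identifier,
truth,parameter,Flat parameter name (see cartpop::parameter_names()),
truth,value,Ground-truth parameter value used to simulate this patient,model units
groups,patient_id,Synthetic patient identifier,
groups,group,good/poor responder label when the cohort was generated in responder mode; NA otherwise,
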