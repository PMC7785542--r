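verbatim_pattern,normalized_term
hepatotoxicity,hepatotoxicity
hepatic_injury,hepatotoxicity
liver_toxicity,hepatotoxicity
liver_injury,hepatotoxicity
drug_induced_liver_injury,hepatotoxicity
transaminase_elevation,hepatotoxicity
qt_prolongation,qt_prolongation
qtc_prolongation,qt_prolongation
prolonged_qt_interval,qt_prolongation
neutropenia,neutropenia
low_neutrophil_count,neutropenia
febrile_neutropenia,neutropenia
thrombocytopenia,thrombocytopenia
low_platelet_count,thrombocytopenia
anaphylaxis,hypersensitivity
hypersensitivity,hypersensitivity
allergic_reaction,hypersensitivity
infusion_reaction,infusion_reaction
infusion_related_reaction,infusion_reaction
embryo_fetal_toxicity,embryofetal_toxicity
embryofetal_toxicity,embryofetal_toxicity
fetal_harm,embryofetal_toxicity
teratogenicity,embryofetal_toxicity
nephrotoxicity,nephrotoxicity
renal_toxicity,nephrotoxicity
renal_impairment,nephrotoxicity
acute_kidney_injury,nephrotoxicity
cytokine_release_syndrome,cytokine_release_syndrome
crs,cytokine_release_syndrome
neurotoxicity,neurotoxicity
neurological_toxicity,neurotoxicity
cardiotoxicity,cardiotoxicity
cardiac_toxicity,cardiotoxicity
heart_failure,cardiotoxicity
myelosuppression,myelosuppression
bone_marrow_suppression,myelosuppression
immunogenicity,immunogenicity
anti_drug_antibodies,immunogenicity
serious_infection,serious_infection
serious_infections,serious_infection
opportunistic_infection,serious_infection
malignancy,secondary_malignancy
secondary_malignancy,secondary_malignancy
suicidal_ideation,suicidality
suicidality,suicidality
somnolence,somnolence
sedation,somnolence
hypertension,hypertension
elevated_blood_pressure,hypertension
diarrhea,diarrhea
diarrhoea,diarrhea
nausea,nausea
vomiting,vomiting
headache,headache
rash,rash
skin_reaction,rash
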