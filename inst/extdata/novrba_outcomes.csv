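component_id,outcome_name,direction
calcium,colorectal_cancer,beneficial
fiber_insoluble,colorectal_cancer,beneficial
fiber_insoluble,cardiovascular_disease,beneficial
iron,iron_deficiency_anemia,beneficial
magnesium,type_2_diabetes,beneficial
sodium,cardiovascular_disease,adverse
sodium,gastric_cancer,adverse
vitamin_b12,megaloblastic_anemia,beneficial
zinc,impaired_immune_function,beneficial
b_cereus,toxin_mediated_gastroenteritis,adverse
c_perfringens,gastroenteritis,adverse
cronobacter_sakazakii,invasive_infection,adverse
listeria_monocytogenes,listeriosis,adverse
salmonella,salmonellosis,adverse
toxoplasma_gondii,congenital_toxoplasmosis,adverse
inorganic_arsenic,lung_cancer,adverse
inorganic_arsenic,skin_lesions,adverse
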