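component_id,food_id,has_dose_response,has_incidence,has_source_attribution,has_intake_data,has_composition_or_contamination,has_daly_per_case
carbohydrates,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
carbohydrates,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
fiber,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
fiber,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
fiber_insoluble,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
fiber_insoluble,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
fiber_soluble,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
fiber_soluble,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
aluminum,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
aluminum,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
calcium,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
calcium,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
chloride,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
chloride,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
chromium,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
chromium,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
copper,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
copper,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
iodine,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
iodine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
iron,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
iron,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
magnesium,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
magnesium,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
manganese,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
manganese,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
potassium,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
potassium,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
selenium,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
selenium,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
sodium,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
sodium,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
sulfur,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
sulfur,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
zinc,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
zinc,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
folate,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
folate,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
niacin,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
niacin,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
pantothenic_acid,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
pantothenic_acid,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
retinol,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
retinol,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
thiamin,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
thiamin,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_b12,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_b12,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
riboflavin,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
riboflavin,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
pyridoxine,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
pyridoxine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_c,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_c,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_d3,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_d3,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_e,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
vitamin_e,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_mufa,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_mufa,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_pufa,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_pufa,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_n3_fa,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
total_n3_fa,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
total_n6_fa,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
total_n6_fa,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
total_sfa,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
total_sfa,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
cholesterol,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
alanine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
cystine_cysteine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
histidine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
lysine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
methionine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
phenylalanine,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
tryptophan,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
b_cereus,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
campylobacter,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
c_botulinum,ad,TRUE,FALSE,TRUE,TRUE,TRUE,TRUE
c_perfringens,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
cronobacter_sakazakii,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
ehec,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
listeria_monocytogenes,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
salmonella,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
s_aureus,ad,TRUE,TRUE,FALSE,TRUE,TRUE,TRUE
vibrio,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
yersinia_enterocolitica,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
hepatitis_a,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
norovirus,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
histamine,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
b_cereus,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
campylobacter,beef,TRUE,TRUE,FALSE,TRUE,TRUE,TRUE
c_perfringens,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
cronobacter_sakazakii,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
ehec,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
listeria_monocytogenes,beef,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
salmonella,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
s_aureus,beef,TRUE,TRUE,FALSE,TRUE,TRUE,TRUE
yersinia_enterocolitica,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
hepatitis_e,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
norovirus,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
rotavirus,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
cryptosporidium,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
toxoplasma_gondii,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_pcb,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
pfr_flame_retardants,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
oxychlordane,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
pbde,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
mercury,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
cadmium,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
lead,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
inorganic_arsenic,ad,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
aluminum_contam,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
nickel,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
chromium_contam,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
pesticide_mix,ad,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
total_pcb,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
dioxin_dl_pcb,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
organochlorine_compounds,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
methylmercury,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
cadmium,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
lead,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
inorganic_arsenic,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
aluminum_contam,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
nickel,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
chromium_contam,beef,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
pah,beef,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE
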