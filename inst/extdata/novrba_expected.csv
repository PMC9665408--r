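component_id,food_id,domain,stage,printed
calcium,ad,nutrition,shortlist,TRUE
copper,ad,nutrition,shortlist,TRUE
fiber_insoluble,ad,nutrition,shortlist,TRUE
iron,ad,nutrition,shortlist,TRUE
magnesium,ad,nutrition,shortlist,TRUE
selenium,ad,nutrition,shortlist,TRUE
sodium,ad,nutrition,shortlist,TRUE
total_n3_fa,ad,nutrition,shortlist,TRUE
total_n6_fa,ad,nutrition,shortlist,TRUE
zinc,ad,nutrition,shortlist,TRUE
iron,beef,nutrition,shortlist,TRUE
niacin,beef,nutrition,shortlist,TRUE
selenium,beef,nutrition,shortlist,TRUE
sodium,beef,nutrition,shortlist,TRUE
total_sfa,beef,nutrition,shortlist,TRUE
thiamin,beef,nutrition,shortlist,TRUE
vitamin_b12,beef,nutrition,shortlist,TRUE
vitamin_d3,beef,nutrition,shortlist,TRUE
zinc,beef,nutrition,shortlist,TRUE
b_cereus,ad,microbiology,shortlist,TRUE
c_botulinum,ad,microbiology,shortlist,TRUE
c_perfringens,ad,microbiology,shortlist,TRUE
cronobacter_sakazakii,ad,microbiology,shortlist,TRUE
listeria_monocytogenes,ad,microbiology,shortlist,TRUE
salmonella,ad,microbiology,shortlist,TRUE
s_aureus,ad,microbiology,shortlist,TRUE
c_perfringens,beef,microbiology,shortlist,TRUE
campylobacter,beef,microbiology,shortlist,TRUE
listeria_monocytogenes,beef,microbiology,shortlist,TRUE
salmonella,beef,microbiology,shortlist,TRUE
s_aureus,beef,microbiology,shortlist,TRUE
toxoplasma_gondii,beef,microbiology,shortlist,TRUE
inorganic_arsenic,ad,toxicology,shortlist,TRUE
pah,beef,toxicology,shortlist,TRUE
inorganic_arsenic,beef,toxicology,shortlist,FALSE
calcium,ad,nutrition,finallist,TRUE
fiber_insoluble,ad,nutrition,finallist,TRUE
iron,ad,nutrition,finallist,TRUE
magnesium,ad,nutrition,finallist,TRUE
sodium,ad,nutrition,finallist,TRUE
vitamin_b12,ad,nutrition,finallist,TRUE
zinc,ad,nutrition,finallist,TRUE
calcium,beef,nutrition,finallist,TRUE
fiber_insoluble,beef,nutrition,finallist,TRUE
iron,beef,nutrition,finallist,TRUE
magnesium,beef,nutrition,finallist,TRUE
sodium,beef,nutrition,finallist,TRUE
vitamin_b12,beef,nutrition,finallist,TRUE
zinc,beef,nutrition,finallist,TRUE
b_cereus,ad,microbiology,finallist,TRUE
c_perfringens,ad,microbiology,finallist,TRUE
cronobacter_sakazakii,ad,microbiology,finallist,TRUE
listeria_monocytogenes,ad,microbiology,finallist,TRUE
salmonella,ad,microbiology,finallist,TRUE
c_perfringens,beef,microbiology,finallist,TRUE
salmonella,beef,microbiology,finallist,TRUE
toxoplasma_gondii,beef,microbiology,finallist,TRUE
inorganic_arsenic,beef,toxicology,finallist,TRUE
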