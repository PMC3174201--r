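#scale=sqrt_weekly
# Pharmacogenetic warfarin dosing coefficients of the International
# Warfarin Pharmacogenetics Consortium algorithm (Klein et al. 2009,
# N Engl J Med 360:753-764, supplementary appendix). Linear predictor is
# sqrt(weekly dose in mg). Genotype and status terms are 0/1 indicators.
term	coefficient
(Intercept)	5.6044
age_decades	-0.2614
height_cm	0.0087
weight_kg	0.0128
vkorc1_ag	-0.8677
vkorc1_aa	-1.6974
vkorc1_unknown	-0.4854
cyp2c9_12	-0.5211
cyp2c9_13	-0.9357
cyp2c9_22	-1.0616
cyp2c9_23	-1.9206
cyp2c9_33	-2.3312
cyp2c9_unknown	-0.2188
race_asian	-0.1092
race_black	-0.2760
race_mixed_missing	-0.1032
enzyme_inducer	1.1816
amiodarone	-0.5503
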