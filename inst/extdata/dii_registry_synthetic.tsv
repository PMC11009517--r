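name	unit	global_mean	global_sd	effect_score	energy_adjust
energy	kcal/d	2100	600	0.18	FALSE
carbohydrate	g/1000kcal	140	25	0.10	TRUE
vitamin_a	RE/1000kcal	420	120	-0.40	TRUE
total_fat	g/1000kcal	32	7	0.30	TRUE
protein	g/1000kcal	36	8	0.02	TRUE
trans_fat	g/1000kcal	1.6	0.9	0.23	TRUE
saturated_fat	g/1000kcal	11	3.5	0.37	TRUE
folic_acid	ug/1000kcal	160	55	-0.19	TRUE
pufa	g/1000kcal	7.5	2.6	-0.25	TRUE
mufa	g/1000kcal	11	3.2	-0.01	TRUE
omega3	g/1000kcal	0.8	0.45	-0.44	TRUE
omega6	g/1000kcal	4.5	1.8	-0.16	TRUE
fibre	g/1000kcal	9.5	3.2	-0.66	TRUE
riboflavin	mg/1000kcal	0.85	0.30	-0.07	TRUE
cholesterol	mg/1000kcal	120	45	0.11	TRUE
niacin	mg/1000kcal	9.5	3.0	-0.25	TRUE
vitamin_d	ug/1000kcal	2.5	1.4	-0.45	TRUE
thiamin	mg/1000kcal	0.80	0.27	-0.10	TRUE
vitamin_c	mg/1000kcal	55	28	-0.42	TRUE
vitamin_e	mg/1000kcal	4.2	1.9	-0.42	TRUE
vitamin_b12	ug/1000kcal	2.2	1.1	0.11	TRUE
vitamin_b6	mg/1000kcal	0.75	0.28	-0.36	TRUE
magnesium	mg/1000kcal	150	45	-0.48	TRUE
iron	mg/1000kcal	7.5	2.4	0.03	TRUE
selenium	ug/1000kcal	34	14	-0.19	TRUE
zinc	mg/1000kcal	4.8	1.5	-0.31	TRUE
caffeine	mg/1000kcal	45	35	-0.11	TRUE
tea	g/1000kcal	180	140	-0.54	TRUE
beta_carotene	ug/1000kcal	1700	900	-0.58	TRUE
isoflavones	mg/1000kcal	0.60	0.45	-0.59	TRUE
flavones	mg/1000kcal	0.70	0.45	-0.62	TRUE
flavanones	mg/1000kcal	5.5	3.2	-0.25	TRUE
flavonols	mg/1000kcal	9.0	4.5	-0.47	TRUE
anthocyanidins	mg/1000kcal	8.0	4.8	-0.13	TRUE
garlic	g/1000kcal	1.8	1.3	-0.41	TRUE
onion	g/1000kcal	14	9	-0.30	TRUE
pepper	g/1000kcal	3.5	2.6	-0.13	TRUE
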