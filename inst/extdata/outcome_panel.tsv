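outcome	group	type	cases	cases_pct	n
miscarriage	pregnancy_loss	primary	89086	18	486217
stillbirth	pregnancy_loss	primary	6331	3	207670
sporadic_miscarriage	pregnancy_loss	secondary	55888	23	241159
recurrent_miscarriage	pregnancy_loss	secondary	6233	2	321756
gestational_diabetes	maternal_morbidity	primary	24752	3	714899
perinatal_depression	maternal_morbidity	primary	17076	15	115797
induction_of_labour	labour	primary	14495	15	95239
rupture_of_membranes	labour	primary	21839	7	310621
caesarean_section	labour	primary	33909	14	233969
emergency_c_section	labour	secondary	9165	10	90438
elective_c_section	labour	secondary	6004	7	87283
low_birth_weight	offspring_birth	primary	19180	7	283151
high_birth_weight	offspring_birth	primary	6679	3	266835
small_for_gestational_age	offspring_birth	primary	7448	8	96305
large_for_gestational_age	offspring_birth	primary	10468	11	96305
preterm_birth	offspring_birth	primary	18225	6	285722
post_term_birth	offspring_birth	primary	27213	7	414667
low_apgar_1min	offspring_birth	primary	4950	6	86668
low_apgar_5min	offspring_birth	primary	821	1	74368
nicu_admission	offspring_birth	primary	6996	9	77285
spontaneous_preterm_birth	offspring_birth	secondary	17176	6	272940
very_preterm_birth	offspring_birth	secondary	1107	1	77683
birth_weight	offspring_birth	secondary	NA	NA	289846
gestational_age	offspring_birth	secondary	NA	NA	211416
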