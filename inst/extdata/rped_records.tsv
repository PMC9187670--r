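# Retinal pigment epithelial detachment (RPED) events: one row per affected
# eye, times in months from treatment start. Subject identifiers are
# anonymised placeholders (R01-R11).
subject	eye	time_to_diagnosis_months	duration_months	outcome	discontinuation_reason
R01	right	6.7	0.5	improved	AE_not_RPED
R01	left	6.7	0.5	improved	AE_not_RPED
R02	right	1.0	0.5	completely_resolved	disease_progression
R02	left	1.0	0.5	completely_resolved	disease_progression
R03	right	1.9	1.2	worsened_on_reintroduction	AE_RPED
R03	left	1.9	1.2	worsened_on_reintroduction	AE_RPED
R04	right	1.9	0.5	completely_resolved	disease_progression
R05	right	0.9	0.5	completely_resolved	disease_progression
R06	right	2.0	0.8	completely_resolved	AE_including_RPED
R06	left	0.9	1.9	completely_resolved	AE_including_RPED
R07	right	0.8	0.9	improved	AE_including_RPED
R07	left	0.8	0.9	improved	AE_including_RPED
R08	right	0.8	0.4	improved	AE_including_RPED
R09	right	0.9	2.1	completely_resolved	AE_including_RPED
R09	left	0.9	2.1	completely_resolved	AE_including_RPED
R10	right	1.9	1.2	completely_resolved	disease_progression
R11	right	2.3	0.7	completely_resolved	AE_not_RPED
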