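icd9	icd10	note
307.40	F51.9	nonorganic sleep disorder, unspecified
307.41	F51.01	transient disorder of initiating or maintaining sleep
307.42	F51.02	persistent disorder of initiating or maintaining sleep
307.43	F51.11	transient disorder of initiating or maintaining wakefulness
307.44	F51.12	persistent disorder of initiating or maintaining wakefulness
307.45	G47.20	circadian rhythm sleep disorder
307.46	F51.3	sleepwalking
307.47	F51.8	other dysfunctions of sleep stages or arousal
307.48	F51.4	repetitive intrusions of sleep
307.49	F51.9	other specific disorders of sleep
327.23	G47.33	obstructive sleep apnea
333.94	G25.81	restless legs syndrome
780.50	G47.9	sleep disturbance, unspecified
780.51	G47.33	insomnia with sleep apnea
780.52	G47.00	insomnia, unspecified
780.53	G47.33	hypersomnia with sleep apnea
780.54	G47.10	hypersomnia, unspecified
780.55	G47.20	disruption of 24-hour sleep-wake cycle
780.56	G47.8	dysfunctions associated with sleep stages or arousal
780.57	G47.30	unspecified sleep apnea
780.58	G47.61	sleep related movement disorder
780.59	G47.8	other sleep disturbances
786.00	R06.00	respiratory abnormality, unspecified
786.01	R06.4	hyperventilation
786.02	R06.01	orthopnea
786.03	R06.81	apnea
786.04	R06.3	Cheyne-Stokes respiration
786.05	R06.02	shortness of breath
786.06	R06.82	tachypnea
786.07	R06.2	wheezing
786.09	R06.89	other respiratory abnormality
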