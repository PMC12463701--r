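pattern	match	outcome	note
O82	prefix	cesarean	encounter for cesarean delivery without indication
O75.82	exact	cesarean	onset of labor after 37 weeks with cesarean delivery
Z38.01	exact	cesarean	single liveborn, delivered by cesarean (infant record)
O24.4	prefix	gestational_diabetes	gestational diabetes mellitus
O13	prefix	gestational_hypertension	gestational hypertension without significant proteinuria
O14	prefix	preeclampsia	pre-eclampsia
F53.0	exact	postpartum_depression	postpartum depression
Z37.1	exact	stillbirth	single stillbirth
P95	prefix	stillbirth	stillbirth of unspecified cause
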