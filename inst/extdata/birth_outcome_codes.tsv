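pattern	match	axis	level	note
P05.1	prefix	size_for_ga	SGA	small for gestational age
P08.0	prefix	size_for_ga	LGA	exceptionally large newborn (>4500 g)
P07.0	prefix	birthweight	LBW	extremely low birthweight (<1000 g)
P07.1	prefix	birthweight	LBW	other low birthweight (1000-2499 g)
P08.1	prefix	birthweight	HBW	other heavy for gestational age newborn (4000-4499 g)
P07.3	prefix	gestation_period	preterm	preterm newborn, 28-36 completed weeks
P08.21	exact	gestation_period	post_term	post-term newborn, over 40 to 42 completed weeks
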