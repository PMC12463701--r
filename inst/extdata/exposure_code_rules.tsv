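pattern	match	family	note
F51	prefix	F51	sleep disorders not due to a substance or known physiological condition
G25.81	exact	G25	restless leg syndrome (only qualifying G25 subcode)
G47	prefix	G47	sleep disorders
R06	prefix	R06	breathing abnormalities
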