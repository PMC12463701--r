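code	weeks	note
765.21	23	less than 24 completed weeks
765.22	24	24 completed weeks
765.23	26	25-26 completed weeks, midpoint rounded up
765.24	28	27-28 completed weeks, midpoint rounded up
765.25	30	29-30 completed weeks, midpoint rounded up
765.26	32	31-32 completed weeks, midpoint rounded up
765.27	34	33-34 completed weeks, midpoint rounded up
765.28	36	35-36 completed weeks, midpoint rounded up
765.29	37	37 or more completed weeks
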