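population	cohort	n	percentile	lod
AA	African-American controls (GAIN)	889	50	-0.39
AA	African-American controls (GAIN)	889	90	0.67
AA	African-American controls (GAIN)	889	95	0.82
AA	African-American controls (GAIN)	889	99	2.32
EA	European-American controls (GAIN)	1433	50	-0.39
EA	European-American controls (GAIN)	1433	90	0.24
EA	European-American controls (GAIN)	1433	95	0.82
EA	European-American controls (GAIN)	1433	99	3.24
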