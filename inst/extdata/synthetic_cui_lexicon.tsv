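term	cui	description	score
study	C0008972	Clinical Study	0.95
prevalence	C0033105	Prevalence	0.90
impairment	C0684336	Impairment	0.85
cognitive impairment	C0338656	Cognitive Impairment	0.97
populations	C0032659	Population Group	0.90
confirm	C1456348	Confirm	0.80
highlight	C2607870	Highlight	0.60
attention	C0004268	Attention	0.88
risk factors	C0035648	Risk Factor	0.93
warrant	C1710187	Warrant	0.55
dementia	C0497327	Dementia finding	0.98
dementia	C0011265	Dementia	0.98
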