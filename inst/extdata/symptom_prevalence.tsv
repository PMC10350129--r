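symptom	abbr	cohort_class	present	absent	printed_pct	note
Depressed mood	Dep	clinical	21681	1748	93
Depressed mood	Dep	community	107956	99480	52
Depressed mood	Dep	ukb_touchscreen	71964	57130	56
Anhedonia	Anh	clinical	24732	2801	90
Anhedonia	Anh	community	181113	126167	39	printed percent inconsistent with printed counts (59%)
Anhedonia	Anh	ukb_touchscreen	46952	80366	37
Weight loss / decrease in appetite	AppDec	clinical	9265	14594	39
Weight loss / decrease in appetite	AppDec	community	39453	36497	52
Weight gain / increase in appetite	AppInc	clinical	7902	13167	38
Weight gain / increase in appetite	AppInc	community	22612	36489	38
Insomnia	SleDec	clinical	18917	6573	74
Insomnia	SleDec	community	73144	19851	79
Hypersomnia	SleInc	clinical	10586	11050	49
Hypersomnia	SleInc	community	20125	20055	50
Psychomotor agitation	MotoInc	clinical	10447	12372	46
Psychomotor agitation	MotoInc	community	113	3181	3
Psychomotor slowing	MotoDec	clinical	12701	11214	53
Psychomotor slowing	MotoDec	community	299	2995	9
Fatigue	Fatig	clinical	23941	2497	91
Fatigue	Fatig	community	85304	16736	84
Feelings of worthlessness / guilt	Guilt	clinical	21921	3888	85
Feelings of worthlessness / guilt	Guilt	community	61757	43570	59
Diminished concentration	Conc	clinical	23974	2386	91
Diminished concentration	Conc	community	75190	23416	76
Recurrent thoughts of death or suicide	Sui	clinical	18170	9609	65
Recurrent thoughts of death or suicide	Sui	community	46984	58885	44
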