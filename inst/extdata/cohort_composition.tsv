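dimension	class	population	n
ER	ER+	MEX	35
ER	ER-	MEX	14
ER	ER+	VIE	5
ER	ER-	VIE	13
PR	PR+	MEX	31
PR	PR-	MEX	18
PR	PR+	VIE	6
PR	PR-	VIE	12
HER2	HER2+	MEX	8
HER2	HER2-	MEX	41
HER2	HER2+	VIE	0
HER2	HER2-	VIE	1
Grade	GradeII	MEX	25
Grade	GradeIII	MEX	13
Grade	GradeII	VIE	0
Grade	GradeIII	VIE	13
Stage	StageII	MEX	32
Stage	StageIII	MEX	10
Stage	StageII	VIE	38
Stage	StageIII	VIE	8
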