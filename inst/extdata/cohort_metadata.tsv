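# Per-disease subject metadata for the same studies, pooled over cohorts.
disease	group	total	female	male	age_avg	bmi_avg
T2D	case	271	95	59	59.16	25.60
T2D	control	231	77	66	47.36	23.49
obesity	case	278	126	124	56.79	33.55
obesity	control	263	107	105	56.12	23.49
ACVD	case	219	33	79	62.35	24.83
ACVD	control	181	51	40	60.70	24.75
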