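# Per-cohort overview of the metabolic disease metagenome studies:
# six published case/control cohorts covering type 2 diabetes (T2D),
# obesity and atherosclerotic cardiovascular disease (ACVD).
cohort	disease	region	n_case	n_control	accessions	platform
T2D cohort 1	T2D	China	71	192	SRA045646 SRA050230	Illumina GAIIx and HiSeq 2000
T2D cohort 2	T2D	Sweden	93	39	ERP002469	Illumina HiSeq2000
Obesity cohort 1	obesity	Denmark	71	89	ERA000116	Illumina
Obesity cohort 2	obesity	Denmark	207	174	ERP003612	Illumina
ACVD cohort 1	ACVD	China	214	171	ERP023788	Illumina HiSeq2000
ACVD cohort 2	ACVD	Sweden	5	10	SRA059451	Illumina HiSeq2000
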