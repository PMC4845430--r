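PTEN	PTEN
PTEN	MMAC1
PTEN	phosphatase and tensin homolog
BRCA1	BRCA1
BRCA1	breast cancer type 1 susceptibility protein
BRCA2	BRCA2
ESR1	ESR1
ESR1	estrogen receptor alpha
ERBB2	ERBB2
ERBB2	HER2
ERBB2	receptor tyrosine-protein kinase erbB-2
PGR	PGR
PGR	progesterone receptor
EGF	EGF
EGF	epidermal growth factor
CDKN2A	CDKN2A
TP53	TP53
TP53	tumor protein p53
MYLIP	MYLIP
CEACAM3	CEACAM3
CTSD	CTSD
SLC20A2	SLC20A2
CDH1	CDH1
ACAD9	ACAD9
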