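# Synthetic 38-candidate sarcoma fusion panel.
# Gene pairs are curated from the sarcoma fusion-gene literature; transcript
# variants and exon counts are plausible stand-ins, NOT transcript-database
# values. The panel reproduces the size (38 candidates) and the
# partner-sharing structure (e.g. EWSR1, FUS, SS18, NR4A3 recur) that the
# desk-scale experiments depend on.
fusion_id	gene_a	variant_a	n_exons_a	gene_b	variant_b	n_exons_b
EWSR1-FLI1	EWSR1	v1	17	FLI1	v1	9
EWSR1-ERG	EWSR1	v1	17	ERG	v1	11
EWSR1-ETV1	EWSR1	v1	17	ETV1	v1	13
EWSR1-ETV4	EWSR1	v1	17	ETV4	v1	13
EWSR1-FEV	EWSR1	v1	17	FEV	v1	3
EWSR1-NR4A3	EWSR1	v1	17	NR4A3	v1	10
EWSR1-WT1	EWSR1	v1	17	WT1	v1	10
EWSR1-ATF1	EWSR1	v1	17	ATF1	v1	7
EWSR1-DDIT3	EWSR1	v1	17	DDIT3	v1	4
EWSR1-CREB1	EWSR1	v1	17	CREB1	v1	8
EWSR1-POU5F1	EWSR1	v1	17	POU5F1	v1	5
EWSR1-ZNF444	EWSR1	v1	17	ZNF444	v1	5
EWSR1-PBX1	EWSR1	v1	17	PBX1	v1	9
FUS-DDIT3	FUS	v1	15	DDIT3	v1	4
FUS-CREB3L2	FUS	v1	15	CREB3L2	v1	12
FUS-CREB3L1	FUS	v1	15	CREB3L1	v1	12
FUS-ATF1	FUS	v1	15	ATF1	v1	7
FUS-ERG	FUS	v1	15	ERG	v1	11
FUS-FEV	FUS	v1	15	FEV	v1	3
TAF15-NR4A3	TAF15	v1	16	NR4A3	v1	10
TCF12-NR4A3	TCF12	v1	21	NR4A3	v1	10
TFG-NR4A3	TFG	v1	8	NR4A3	v1	10
SS18-SSX1	SS18	v1	11	SSX1	v1	9
SS18-SSX2	SS18	v1	11	SSX2	v1	9
SS18-SSX4	SS18	v1	11	SSX4	v1	9
SS18L1-SSX1	SS18L1	v1	11	SSX1	v1	9
PAX3-FOXO1	PAX3	v1	10	FOXO1	v1	3
PAX7-FOXO1	PAX7	v1	9	FOXO1	v1	3
PAX3-NCOA1	PAX3	v1	10	NCOA1	v1	21
COL1A1-PDGFB	COL1A1	v1	51	PDGFB	v1	7
ETV6-NTRK3	ETV6	v1	8	NTRK3	v1	20
ASPSCR1-TFE3	ASPSCR1	v1	13	TFE3	v1	10
JAZF1-SUZ12	JAZF1	v1	5	SUZ12	v1	16
JAZF1-PHF1	JAZF1	v1	5	PHF1	v1	15
EPC1-PHF1	EPC1	v1	14	PHF1	v1	15
HEY1-NCOA2	HEY1	v1	5	NCOA2	v1	23
CIC-DUX4	CIC	v1	20	DUX4	v1	3
BCOR-CCNB3	BCOR	v1	15	CCNB3	v1	12
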