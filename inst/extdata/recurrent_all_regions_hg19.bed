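chr1	47681961	47698007	TAL1
chr1	47715814	47779819	STIL
chr5	170736286	170739138	TLX3
chr7	50344377	50472799	IKZF1
chr7	92234234	92465908	CDK6
chr9	21967750	21995300	CDKN2A
chr9	22002901	22009280	CDKN2B
chr9	36833271	37034103	PAX5
chr12	6775641	6798541	ZNF384
chr12	25358179	25403854	KRAS
chr19	1609288	1652328	TCF3
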