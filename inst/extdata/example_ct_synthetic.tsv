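# neurocal-table v1 kind=ct_table (synthetic example, not study data)
gene	sample	replicate	ct
GAPDH	NSC	1	19.27
GAPDH	NSC	2	18.86
GAPDH	NSC	3	18.92
STIM1	NSC	1	25.95
STIM1	NSC	2	25.88
STIM1	NSC	3	25.89
ORAI1	NSC	1	27.09
ORAI1	NSC	2	26.99
ORAI1	NSC	3	27.02
ITPR1	NSC	1	25.26
ITPR1	NSC	2	25.04
ITPR1	NSC	3	25.33
TUBB3	NSC	1	24.27
TUBB3	NSC	2	24.04
TUBB3	NSC	3	24.23
SYN	NSC	1	28.06
SYN	NSC	2	27.89
SYN	NSC	3	27.96
MAP2	NSC	1	26
MAP2	NSC	2	26.12
MAP2	NSC	3	26.1
NES	NSC	1	22.08
NES	NSC	2	22.16
NES	NSC	3	21.83
GAPDH	DIV45	1	19.15
GAPDH	DIV45	2	19.02
GAPDH	DIV45	3	19.09
STIM1	DIV45	1	24.57
STIM1	DIV45	2	24.38
STIM1	DIV45	3	24.47
ORAI1	DIV45	1	25.4
ORAI1	DIV45	2	25.59
ORAI1	DIV45	3	25.51
ITPR1	DIV45	1	23.49
ITPR1	DIV45	2	23.45
ITPR1	DIV45	3	23.43
TUBB3	DIV45	1	22.62
TUBB3	DIV45	2	22.37
TUBB3	DIV45	3	22.48
SYN	DIV45	1	26.54
SYN	DIV45	2	26.65
SYN	DIV45	3	26.42
MAP2	DIV45	1	24.47
MAP2	DIV45	2	24.34
MAP2	DIV45	3	24.45
NES	DIV45	1	21.95
NES	DIV45	2	22.16
NES	DIV45	3	22.07
GAPDH	DIV60	1	19.01
GAPDH	DIV60	2	19.11
GAPDH	DIV60	3	18.97
STIM1	DIV60	1	24
STIM1	DIV60	2	24.04
STIM1	DIV60	3	24.2
ORAI1	DIV60	1	25.09
ORAI1	DIV60	2	25.06
ORAI1	DIV60	3	24.81
ITPR1	DIV60	1	23.04
ITPR1	DIV60	2	23.02
ITPR1	DIV60	3	22.89
TUBB3	DIV60	1	22.01
TUBB3	DIV60	2	22.02
TUBB3	DIV60	3	22.07
SYN	DIV60	1	26.08
SYN	DIV60	2	26.04
SYN	DIV60	3	26.13
MAP2	DIV60	1	24.09
MAP2	DIV60	2	24.14
MAP2	DIV60	3	24.15
NES	DIV60	1	22.08
NES	DIV60	2	22.05
NES	DIV60	3	21.89
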