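# neurocal-table v1 kind=de_table (synthetic example, not study data)
gene	log2fc	p	fdr
CACNA1A	-0.652	0.224	0.658
CACNA1B	1.105	0.238	0.567
CACNA1C	-1.35	0.316	0.864
CACNA1D	0.429	0.223	0.473
CACNA1E	0.622	0.255	0.41
CACNA1G	2.348	0.0211	0.0633
CACNA1H	1.238	0.228	0.362
CACNA1I	-0.225	0.235	0.66
CACNA2D1	1.834	0.0155	0.0168
CACNA2D2	-0.447	0.274	0.602
CACNB1	1.053	0.258	0.609
CACNB2	-1.59	0.0147	0.0436
CACNB3	2.856	0.0299	0.0599
CACNB4	-2.934	0.0708	0.176
CACNG2	-0.473	0.237	0.669
STIM1	-0.387	0.253	0.753
STIM2	-1.7	0.00927	0.0235
ORAI1	0.117	0.256	0.676
ORAI2	-1.635	0.0597	0.172
ORAI3	-4.101	0.0224	0.0525
TRPC1	-0.328	0.213	0.6
TRPC3	1.417	0.271	0.684
TRPC4	-0.536	0.232	0.458
TRPC5	-2.928	0.00662	0.00993
TRPC6	1.489	0.221	0.38
ITPR1	-2.821	0.0203	0.0206
ITPR2	0.934	0.234	0.344
ITPR3	-0.239	0.207	0.251
RYR1	0.934	0.203	0.451
RYR2	0.996	0.204	0.288
GENE01	1.79	0.0765	0.109
GENE02	0.558	0.281	0.29
GENE03	2.016	0.0587	0.0972
GENE04	-4.146	0.00488	0.00751
GENE05	2.38	0.0919	0.26
GENE06	-1.449	0.252	0.463
GENE07	0.336	0.215	0.512
GENE08	1.841	0.0649	0.182
GENE09	-3.343	0.00792	0.0112
GENE10	0.897	0.203	0.39
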