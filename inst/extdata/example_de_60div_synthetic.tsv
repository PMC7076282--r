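# neurocal-table v1 kind=de_table (synthetic example, not study data)
gene	log2fc	p	fdr
CACNA1A	-2.264	0.0928	0.179
CACNA1B	-0.881	0.23	0.549
CACNA1C	-0.673	0.205	0.546
CACNA1D	-1.694	0.0268	0.0743
CACNA1E	-0.292	0.254	0.45
CACNA1G	-2.861	0.0176	0.0296
CACNA1H	-1.553	0.0936	0.175
CACNA1I	-3.867	0.057	0.124
CACNA2D1	0.626	0.213	0.221
CACNA2D2	0.937	0.233	0.636
CACNB1	-0.277	0.245	0.672
CACNB2	2.36	0.0616	0.105
CACNB3	-1.552	0.00198	0.00557
CACNB4	-0.214	0.312	0.754
CACNG2	3.339	0.0264	0.0556
STIM1	-0.516	0.235	0.501
STIM2	3.949	0.0055	0.0134
ORAI1	-1.123	0.207	0.447
ORAI2	1.915	0.0243	0.0388
ORAI3	2.89	0.00637	0.00644
TRPC1	0.679	0.251	0.332
TRPC3	1.762	0.0469	0.105
TRPC4	1.807	0.00519	0.0127
TRPC5	1.5	0.291	0.436
TRPC6	0.718	0.204	0.593
ITPR1	0.505	0.211	0.316
ITPR2	1.154	0.211	0.278
ITPR3	0.837	0.249	0.275
RYR1	-1.322	0.222	0.481
RYR2	5.492	0.0463	0.0671
GENE01	3.535	0.0129	0.0205
GENE02	1.887	0.0352	0.0974
GENE03	-1.571	0.00243	0.00654
GENE04	-2.823	0.00553	0.0117
GENE05	-0.718	0.205	0.482
GENE06	0.992	0.23	0.652
GENE07	-1.717	0.0554	0.102
GENE08	1.025	0.318	0.606
GENE09	-3.5	0.101	0.281
GENE10	-1.479	0.205	0.505
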