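	OTU1	OTU2	OTU3	OTU4	OTU5	OTU6	OTU7	OTU8
S1	96	0	8	85	1488	5104	251	579
S2	37	0	22	731	1577	5109	413	620
S3	37	0	0	275	849	3406	15	483
S4	68	0	0	96	1010	3511	12	1051
S5	262	0	90	159	913	2725	69	1217
S6	46	0	0	643	1663	5683	4	1077
S7	110	0	63	452	1992	4462	41	816
S8	227	0	1	79	2016	6024	93	1245
S9	279	0	0	126	1411	6010	19	1446
S10	51	0	0	121	1067	4950	843	517
S11	725	0	0	349	1119	7145	102	320
S12	223	0	19	172	1268	4797	270	758
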