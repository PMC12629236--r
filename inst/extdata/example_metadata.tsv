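sample	bmi	fat
S1	31.9	70.6
S2	30.47	47.7
S3	30.72	56.4
S4	31.8	72.2
S5	34.58	80.7
S6	32.55	86.6
S7	31.64	68.4
S8	33.44	78
S9	35.34	67.1
S10	31.03	62.3
S11	36.48	54.7
S12	35.01	81.3
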