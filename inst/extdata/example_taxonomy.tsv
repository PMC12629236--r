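taxon	Phylum	Family	Genus
OTU1	P1	F1	G1
OTU2	P1	F1	G2
OTU3	P1	F2	G3
OTU4	P1	F2	G4
OTU5	P2	F3	G5
OTU6	P2	F3	G6
OTU7	P2	F4	G7
OTU8	P2	F4	G8
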