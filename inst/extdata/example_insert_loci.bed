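chrI	1000	2500	YFG1	0	.
chrI	4000	5800	YFG2	0	.
chrI	7000	8200	YFG3	0	.
chrI	11000	13500	YFG4	0	.
chrII	2000	3600	YFG5	0	.
chrII	6000	7900	YFG6	0	.
chrII	9000	10400	YFG7	0	.
chrII	14000	16800	YFG8	0	.
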