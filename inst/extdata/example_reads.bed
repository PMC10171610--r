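chrI	952	2588	YFG1_f01	0	.
chrI	848	2664	YFG1_f02	0	.
chrI	927	2609	YFG1_f03	0	.
chrI	773	2519	YFG1_f04	0	.
chrI	855	2796	YFG1_f05	0	.
chrI	879	2588	YFG1_f06	0	.
chrI	952	2782	YFG1_f07	0	.
chrI	873	2608	YFG1_f08	0	.
chrI	977	2504	YFG1_f09	0	.
chrI	1000	1450	YFG1_p01	0	.
chrI	3789	6091	YFG2_f01	0	.
chrI	3742	5945	YFG2_f02	0	.
chrI	3703	5908	YFG2_f03	0	.
chrI	3977	5996	YFG2_f04	0	.
chrI	3843	5803	YFG2_f05	0	.
chrI	3702	6025	YFG2_f06	0	.
chrI	3865	6014	YFG2_f07	0	.
chrI	4000	4540	YFG2_p01	0	.
chrI	6756	8385	YFG3_f01	0	.
chrI	6887	8337	YFG3_f02	0	.
chrI	6739	8239	YFG3_f03	0	.
chrI	6871	8204	YFG3_f04	0	.
chrI	6998	8232	YFG3_f05	0	.
chrI	6743	8302	YFG3_f06	0	.
chrI	7000	7360	YFG3_p01	0	.
chrI	10773	13534	YFG4_f01	0	.
chrI	10892	13720	YFG4_f02	0	.
chrI	10844	13515	YFG4_f03	0	.
chrI	10925	13719	YFG4_f04	0	.
chrI	10736	13747	YFG4_f05	0	.
chrI	11000	11750	YFG4_p01	0	.
chrII	1883	3748	YFG5_f01	0	.
chrII	1871	3656	YFG5_f02	0	.
chrII	1919	3699	YFG5_f03	0	.
chrII	1891	3897	YFG5_f04	0	.
chrII	1705	3690	YFG5_f05	0	.
chrII	2000	2480	YFG5_p01	0	.
chrII	5732	8107	YFG6_f01	0	.
chrII	5820	8145	YFG6_f02	0	.
chrII	5947	7959	YFG6_f03	0	.
chrII	5713	8184	YFG6_f04	0	.
chrII	6000	6570	YFG6_p01	0	.
chrII	8893	10511	YFG7_f01	0	.
chrII	8875	10471	YFG7_f02	0	.
chrII	9000	9420	YFG7_p01	0	.
chrII	13716	16940	YFG8_f01	0	.
chrII	14000	17005	YFG8_f02	0	.
chrII	14000	14840	YFG8_p01	0	.
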