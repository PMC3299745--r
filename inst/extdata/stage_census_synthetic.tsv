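# Synthetic example stage census (three replicates per treatment, 50 nauplii
# per well), generated with simulate_experiment(synthetic_scenario(seed = 20)).
replicate	treatment	n_start	n_nauplii	n_copepodites
Cipr_r1	Cipr	50	24	16
Cipr_r2	Cipr	50	19	22
Cipr_r3	Cipr	50	20	24
Sulf_r1	Sulf	50	17	29
Sulf_r2	Sulf	50	20	26
Sulf_r3	Sulf	50	20	24
Trim_r1	Trim	50	15	0
Trim_r2	Trim	50	27	0
Trim_r3	Trim	50	22	0
SS_r1	SS	50	14	31
SS_r2	SS	50	19	27
SS_r3	SS	50	17	31
Ac_r1	Ac	50	6	43
Ac_r2	Ac	50	3	42
Ac_r3	Ac	50	11	37
DMSO_r1	DMSO	50	23	16
DMSO_r2	DMSO	50	27	21
DMSO_r3	DMSO	50	21	23
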