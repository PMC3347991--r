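name	family	mature	arm	length	au_pct	mfe	mfei	precursor_id
pde-miR159a	MIR159	UUUGGUUUGAAGGGAGCUCUA	3p	21	53.5	-94.74	0.89	NA
pde-miR162a	MIR162	UCGAUAAACCUCUGCAUCCAG	3p	21	45.0	-49.10	0.80	NA
pde-miR166a	MIR166	UCGGACCAGGCUUCAUUCC	3p	19	45.8	-49.10	0.96	NA
pde-miR166b	MIR166	UCGGACCAGGCUUCAUUCC	3p	19	48.8	-43.40	1.01	NA
pde-miR169a	MIR169	CAGCCAAGGAUGACUUGCCUA	5p	21	58.3	-48.80	1.14	NA
pde-miR171a	MIR171	UGAUUGAGCCGUGCCAAUAUC	3p	21	55.2	-55.20	1.28	NA
pde-miR390a	MIR390	AAGCCCAGGAUGGAUAGCGCC	5p	21	53.7	-40.50	0.92	NA
pde-miR396a	MIR396	UCCCACGGCUUUCUUGAACUU	5p	21	55.1	-43.28	0.90	NA
pde-miR482a	MIR482	UCUUUCCUACUCCUCCCAUUCC	3p	22	52.3	-60.90	0.98	NA
pde-miR482b	MIR482	UCUUCCCUAUUCCUCCCAUUCC	3p	22	52.1	-60.30	1.04	NA
pde-miR482c	MIR482	GGCUUGCGAGGGUAGGAAAAG	5p	21	48.9	-45.20	0.90	NA
pde-miR482d	MIR482	CCUUUCCAACGCCUCCCAUGCC	3p	22	54.8	-46.50	0.76	NA
pde-miR783	MIR783	AUUCUUUGCUGGUUCAUUUUC	3p	21	57.0	-26.80	0.67	NA
pde-miR946a	MIR946	CAGCCCUUCUCCUAUCCACAA	3p	21	59.3	-71.50	1.02	NA
pde-miR947	MIR947	CAUCGGAAUCUGUUACUGUUUC	3p	22	48.7	-70.70	0.94	NA
pde-miR949a	MIR949	UCUCUAGGAAUCAAAUGUGUC	5p	21	47.7	-41.80	0.91	NA
pde-miR949b	MIR949	UCUCCGGGAAUCCAAUGCGCC	5p	21	46.3	-66.30	1.12	NA
pde-miR950a	MIR950	UCUGGUCCACGGUGGUUUAU	5p	20	57.2	-40.90	1.05	NA
pde-miR951	MIR951	UGUUCUUGACGUCUGGACCAC	5p	21	54.8	-43.00	0.83	NA
pde-miR952a	MIR952	AACAGAGCAUGCCAUUGGUG	5p	20	54.0	-232.79	0.96	NA
pde-miR952b	MIR952	AACAGAGCAUGCCAUUGGUG	5p	20	53.9	-214.40	0.99	NA
pde-miR952c	MIR952	AACAGAACAUGCCAUUGGUG	5p	20	54.2	-192.12	0.90	NA
pde-miR1310	MIR1310	GGCAUCGGGGGCGUAACGCCCU	5p	22	47.0	-35.00	0.80	NA
pde-miR1311	MIR1311	UCAGAGUUUUGCCAGUUCCGCC	3p	22	48.8	-43.40	0.99	NA
pde-miR1312a	MIR1312	UUUGGAGAGAAAAUGGCGACAU	3p	22	62.8	-41.50	0.81	NA
pde-miR1313	MIR1313	UACCACUGAAAUUGUUGUUCG	5p	21	58.6	-66.72	0.71	NA
pde-miR1314a	MIR1314	CCGGCCUCGAAUGUUAGGAGAA	3p	22	56.2	-42.30	0.92	NA
pde-miR1448	MIR1448	CUUUCCAACGCCUCCCAUGC	3p	20	54.8	-46.50	0.76	NA
pde-miR2118a	MIR2118	UUUCCAACGCCUCCCAUGCCUA	3p	22	54.8	-46.50	0.76	NA
pde-miR2118b	MIR2118	UUCCCUAUUCCUCCCAUUCCUA	3p	22	49.4	-42.00	0.98	NA
pde-miR3701	MIR3701	UGAACAAUGCCCACCCUUCAUC	3p	22	59.3	-84.10	1.07	NA
pde-miR3704a	MIR3704	GGUCUCGGUGGAGUUGGGAAGA	5p	22	53.8	-49.00	0.98	NA
pde-miR3704b	MIR3704	GGUCUCGAUGGAGUUGGGAAGA	5p	22	54.7	-46.40	0.95	NA
pde-miR3712	MIR3712	UGUGAUCAAGAUCAGACUCCCA	5p	22	59.4	-15.00	0.54	NA
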