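group	nid	taxon	stage	label	tail_length	anal_body_width	cprime_printed	amphid_width	neck_width	amphid_ratio_printed
3	12485	Plectus sp. 3	F	Short	65	26.7	2.4	2	19	0.11
3	13239	Plectus sp. 3	J	Short	35	15	2.3	2.5	17.5	0.14
3	13543	Plectus sp. 3	J	Short	62	28	2.2	NA	NA	NA
3	13030	Plectus sp. 3	J	Short	70	29.4	2.4	2.5	NA	NA
3	13045	Plectus sp. 3	J	Short	61	28.9	2.1	2.5	16.6	0.15
3	13255	Plectus sp. 3	J	Short	65	27.5	2.4	NA	NA	NA
3	13357	Plectus sp. 3	J	Short	66	28.9	2.3	2	17.5	0.11
3	13530	Plectus sp. 3	J	Short	63	25.2	2.5	2	16.2	0.12
3	13538	Plectus sp. 3	J	Short	63	28.9	2.2	2	17	0.12
3	11764	Plectus sp. 3	J	Short	70	29	2.4	2.5	12	0.21
3	11765	Plectus sp. 3	J	Short	74	34	2.2	2	12	0.17
4	13280	Plectus sp. 4	J	Short	77	25	3.1	2.5	17	0.15
4	13608	Plectus sp. 4	F	Short	94	33.6	2.8	2	20.4	0.10
6	13176	Plectus sp. 6	J	Short	72	27.6	2.6	3	15.7	0.19
6	13287	Plectus sp. 6	J	Short	75	27.2	2.8	2.5	17	0.15
6	13425	Plectus sp. 6	J	Short	92	33.6	2.7	3	18.3	0.16
17	13180	Plectus sp. 17	F	Long	129	33.2	3.9	4	17.9	0.22
17	13460	Plectus sp. 17	F	Long	120	28.5	4.2	5	20.4	0.25
18	13465	Plectus sp. 18	F	Long	91.6	17.4	5.3	3.5	13.6	0.26
19	12733	Plectus sp. 19	F	Long	105	18	5.8	3.3	12.5	0.26
20	13403	Plectus sp. 20	F	Long	92.5	17	5.4	3.5	14	0.25
20	13479	Plectus sp. 20	F	Long	94	18.3	5.1	3.5	15.3	0.23
20	13486	Plectus sp. 20	F	Long	85	18.3	4.6	4	14.5	0.28
20	13444	Plectus sp. 20	F	Long	88	16.2	5.4	4	14.9	0.27
20	13440	Plectus sp. 20	J	Long	102	20	5.1	4	15.3	0.26
20	13118	Plectus sp. 20	F	Long	94	18.7	5.0	3	14.9	0.20
20	13133	Plectus sp. 20	J	Long	110	20.8	5.3	4.5	16.2	0.28
20	13203	Plectus sp. 20	F	Long	97	19.6	4.9	3.5	14.9	0.23
20	13225	Plectus sp. 20	F	Long	98	17	5.8	4.5	14.9	0.30
20	13329	Plectus sp. 20	F	Long	96	20.4	4.7	4	14.9	0.27
20	13344	Plectus sp. 20	J	Long	78	13.6	5.7	3.5	11.5	0.30
20	13369	Plectus sp. 20	F	Long	100	17	5.9	4	14.5	0.28
20	13471	Plectus sp. 20	F	Long	94	17.9	5.2	4	13.6	0.29
20	13491	Plectus sp. 20	F	Long	99	19.6	5.0	NA	NA	NA
20	13587	Plectus sp. 20	F	Long	93	19.1	4.9	3.5	15.7	0.22
20	13598	Plectus sp. 20	F	Long	78	17.9	4.4	4	13.6	0.29
20	13601	Plectus sp. 20	F	Long	91	18.3	5.0	3.5	14	0.25
20	13622	Plectus sp. 20	F	Long	88	16.2	5.4	4.5	14	0.32
20	13628	Plectus sp. 20	F	Long	108	20	5.4	3.5	14.9	0.23
20	13641	Plectus sp. 20	F	Long	92	18.3	5.0	3.4	14.9	0.23
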