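# Clinical summary of 24 brain-tumor patients with peritumoral vasogenic edema.
# motor_decline: "yes" = MRC muscle-strength grade <= 4. Seven rows carry "yes"
# exactly as printed in the source table, although its accompanying text counts
# six decliners; the labels below follow the table.
# Case 19's edema volume is printed "1,7875 mm^3" (misplaced thousands
# separator); transcribed as 17875 mm^3 — the published ROC figures for edema
# volume only reproduce under this reading.
case	age	sex	edema_volume_mm3	ltd_mm	motor_decline
1	65	F	18658	37.2	no
2	42	M	8282	12.9	yes
3	49	F	10648	17.4	no
4	38	M	24115	61.3	no
5	36	M	29935	40.6	no
6	57	F	27435	23.5	no
7	55	F	12283	16.4	no
8	32	F	26603	21.6	no
9	43	M	1870	11.3	no
10	56	M	17733	5.0	no
11	55	F	9557	10.0	no
12	37	F	33488	19.4	no
13	72	M	12180	3.8	no
14	51	F	24288	34.7	no
15	51	F	15738	4.8	yes
16	72	F	6045	4.6	yes
17	69	F	30948	36.5	no
18	59	F	5535	15.2	no
19	64	M	17875	16.4	yes
20	38	M	7207	8.7	yes
21	53	F	21523	40.2	no
22	55	F	8680	7.7	no
23	36	F	15620	2.3	yes
24	65	M	19889	12.9	yes
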