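percent_reactive	duration_steps	km	kcat
1	0	-0.850576595	-0.028514453
5	0	-2.996153951	-0.687
5	25	-4.656418568	-0.977
5	50	3.439111157	0.808
5	75	2.918555171	0.625
5	100	-21.79373575	-3.92
10	0	-14.6001318	-6.631944616
15	0	11.51508927	7.623330464
25	0	0.87739	1.08
25	5	1.36829	1.44
25	25	2.45375	2.23
25	50	1.20869	1.06
25	75	0.70036	0.622
25	100	0.531257304	0.452
34	1	3.18977	3.93
50	0	0.71725	1.27
75	0	3.65866	6.49
75	5	3.06473	5.33
75	25	1.13387	2.01
75	50	0.60205	1.07
75	75	0.37565	0.669
75	100	0.29693544	0.506
90	0	4.43222	8.17
95	0	4.49601	8.44
95	25	1.277963717	2.396621333
95	50	0.56747	1.11
95	75	0.34196	0.688
95	100	0.237537579	0.488
100	0	0.75547	1.6
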