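year	cond_surv
6	0.84
7	0.85
8	0.86
9	0.87
10	0.88
11	0.89
12	0.9
13	0.91
14	0.92
15	0.93
16	0.94
17	0.95
18	0.95
19	0.95
20	0.95
21	0.95
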