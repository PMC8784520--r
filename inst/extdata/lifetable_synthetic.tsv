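age	q
64	0.012
65	0.01313
66	0.014367
67	0.01572
68	0.0172
69	0.01882
70	0.020592
71	0.022531
72	0.024653
73	0.026975
74	0.029515
75	0.032295
76	0.035336
77	0.038664
78	0.042305
79	0.046289
80	0.050648
81	0.055418
82	0.060637
83	0.066348
84	0.072596
85	0.079432
86	0.086913
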