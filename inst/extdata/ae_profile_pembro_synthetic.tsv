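ae	incidence	unit_cost	disutility	duration_months
pneumonitis	0.04	18000	0.2	1
severe_skin_reaction	0.031	12000	0.1	0.5
colitis	0.02	15444	0.15	0.7
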