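experiment_id	count	n_total	plating_fraction
control	22	2e+06	1
control	1	2e+06	1
control	0	2e+06	1
control	0	2e+06	1
control	2	2e+06	1
control	1	2e+06	1
control	2	2e+06	1
control	4	2e+06	1
control	0	2e+06	1
control	25	2e+06	1
control	1	2e+06	1
control	0	2e+06	1
mutator	10	2e+06	0.1
mutator	41	2e+06	0.1
mutator	4	2e+06	0.1
mutator	10	2e+06	0.1
mutator	15	2e+06	0.1
mutator	44	2e+06	0.1
mutator	18	2e+06	0.1
mutator	36	2e+06	0.1
mutator	28	2e+06	0.1
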