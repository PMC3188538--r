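clone_id	position	ref	alt	kind	effect
clone_0001	1481	G	T	substitution	missense
clone_0002	493	T	G	substitution	missense
clone_0003	1757	A	T	substitution	missense
clone_0004	566	A	G	substitution	missense
clone_0005	1003	C	A	substitution	missense
clone_0006	26	T	A	substitution	missense
clone_0007	1583	C	G	substitution	missense
clone_0008	1511	T	A	substitution	missense
clone_0009	1399	A	C	substitution	missense
clone_0010	662	C	A	substitution	missense
clone_0011	1022	C	T	substitution	missense
clone_0012	194	G	T	substitution	missense
clone_0013	392	G	A	substitution	chain_terminating
clone_0014	269	T	A	substitution	chain_terminating
clone_0015	1422	-	C	insertion	NA
clone_0016	1367	T	C	substitution	missense
clone_0017	851	A	G	substitution	missense
clone_0018	298	A	G	substitution	missense
clone_0019	218	G	T	substitution	missense
clone_0020	113	A	C	substitution	missense
clone_0021	1661	C	A	substitution	missense
clone_0022	1547	C	G	substitution	missense
clone_0023	626	C	T	substitution	missense
clone_0024	248	T	G	substitution	missense
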