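study_id	rsid	chrom	pos	p_value	trait	phenotype_group	uses_population_controls
Huang2011	rs17376456	5	60000000	3e-15	DR	DR	false
Huang2011	rs2038823	13	97000000	5e-11	DR	DR	false
Imamura2021	rs12630354	3	31000000	7e-10	DR	DR	false
Huang2011	rs4838605	10	50000000	2e-09	DR	DR	false
Huang2011	rs12219125	10	20000000	9e-09	DR	DR	false
Pollack2018	rs202069793	9	107000000	6e-08	DR	DR	false
Huang2011	rs4462262	10	59189178	9e-08	DR	DR	false
Sheu2013	rs3081219	15	53000000	1e-09	PDR	PDR_sight_threatening	false
Meng2018	rs3913535	11	89000000	4e-09	PDR	PDR_sight_threatening	false
Liu2019	rs11018670	11	49000000	1e-08	PDR	PDR_sight_threatening	false
Pollack2018	rs72740408	4	20000000	2e-08	PDR	PDR_sight_threatening	false
Liu2019	rs184340784	6	150000000	4e-08	PDR	PDR_sight_threatening	false
Burdon2015	rs1065386	6	31000000	5e-08	PDR	PDR_sight_threatening	false
Graham2018	rs4726066	7	151000000	5e-08	PDR	PDR_sight_threatening	false
Pollack2018	rs200295620	3	167000000	7e-08	PDR	PDR_sight_threatening	false
Meng2019	rs9966620	18	40000000	7e-08	Diabetic maculopathy	DME_maculopathy	false
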