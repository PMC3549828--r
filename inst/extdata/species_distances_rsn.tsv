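species1	species2	d18s	gapdh	cpsf3	rsn
mouse	human	0.008099	0.083105	0.01452	88.5
chicken	human	0.034382	0.080086	0.052188	85.0
c.elegans	human	0.336445	0.309192	0.642712	68.5
o.sativa	human	0.245416	0.3565	0.674258	61.0
arabidopsis	human	0.240724	0.3788	0.678983	65.5
s.lycopersicum	human	0.232462	0.390498	0.838763	58.0
chicken	mouse	0.035031	0.098663	0.061379	86.0
c.elegans	mouse	0.336259	0.318807	0.649077	67.0
o.sativa	mouse	0.242306	0.376424	0.677389	60.5
arabidopsis	mouse	0.24307	0.40044	0.683073	55.5
s.lycopersicum	mouse	0.233802	0.390069	0.843015	58.0
c.elegans	chicken	0.331649	0.26794	0.63646	67.5
o.sativa	chicken	0.242221	0.338926	0.688556	61.5
arabidopsis	chicken	0.241121	0.353368	0.685943	62.0
s.lycopersicum	chicken	0.231997	0.36337	0.843798	54.0
o.sativa	c.elegans	0.392745	0.388677	0.848847	65.0
arabidopsis	c.elegans	0.3879	0.40471	0.885896	70.5
s.lycopersicum	c.elegans	0.377503	0.387265	0.997973	64.0
arabidopsis	o.sativa	0.054837	0.260299	0.245492	63.5
s.lycopersicum	o.sativa	0.045931	0.273969	0.346818	68.5
s.lycopersicum	arabidopsis	0.031789	0.218126	0.31507	65.5
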