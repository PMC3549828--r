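model	human	mouse	chicken	c.elegans	o.sativa	arabidopsis	s.lycopersicum
human	87	90	90	73	58	86	90
mouse	87	93	90	72	60	75	90
chicken	80	82	96	71	53	78	81
c.elegans	64	62	64	95	60	85	83
o.sativa	64	61	70	70	89	93	98
arabidopsis	45	36	46	56	34	94	79
s.lycopersicum	26	26	27	45	39	52	93
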