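species	method	sn	sp	mcc
human	lda	85	93	0.78
human	lr	86	90	0.77
mouse	lda	91	96	0.87
mouse	lr	92	94	0.86
chicken	lda	87	91	0.78
chicken	lr	87	90	0.77
c.elegans	lda	85	89	0.74
c.elegans	lr	90	85	0.75
o.sativa	lda	88	89	0.77
o.sativa	lr	88	89	0.77
arabidopsis	lda	92	92	0.84
arabidopsis	lr	91	91	0.82
s.lycopersicum	lda	91	92	0.83
s.lycopersicum	lr	90	91	0.81
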