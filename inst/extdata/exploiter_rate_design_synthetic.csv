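concentration,rate_per_h,replicate
0.016,0.0057990735459922,rep1
0.016,0.0058393008890948,rep2
0.016,0.0058453823779677,rep3
0.16,0.0542790180902171,rep1
0.16,0.0546608625756319,rep2
0.16,0.0539632220936946,rep3
0.8,0.209509471271149,rep1
0.8,0.207100012009632,rep2
0.8,0.21180486697379,rep3
1.6,0.329987318766845,rep1
1.6,0.327990060323784,rep2
1.6,0.33234265478163,rep3
4.8,0.517615349009924,rep1
4.8,0.521089164755084,rep2
4.8,0.530429964489795,rep3
9.6,0.610008989037746,rep1
9.6,0.623782125611979,rep2
9.6,0.608162982474889,rep3
16,0.663207926726058,rep1
16,0.666450417526836,rep2
16,0.65912246687927,rep3
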