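concentration,rate_per_h,replicate
0.016,0.00723572119143945,rep1
0.016,0.00729207258146791,rep2
0.016,0.00729977923205182,rep3
0.16,0.0664551993744322,rep1
0.16,0.0660267593318991,rep2
0.16,0.0672879476722521,rep3
0.8,0.236649634999005,rep1
0.8,0.237916553316982,rep2
0.8,0.239098400096232,rep3
1.6,0.357781595623716,rep1
1.6,0.359264572242921,rep2
1.6,0.358984799406477,rep3
4.8,0.52993679748648,rep1
4.8,0.529429155132925,rep2
4.8,0.52114636098268,rep3
9.6,0.59005556978518,rep1
9.6,0.600523390197756,rep2
9.6,0.592955382432772,rep3
16,0.627102990578488,rep1
16,0.633452614582662,rep2
16,0.633504339303441,rep3
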