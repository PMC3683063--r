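concentration,rate_per_h,replicate
0.016,0.0537041372405719,rep1
0.016,0.0541780056132377,rep2
0.016,0.0535170860640503,rep3
0.16,0.289135253985081,rep1
0.16,0.289414143001033,rep2
0.16,0.291923170752181,rep3
0.8,0.473658744826399,rep1
0.8,0.470206459169976,rep2
0.8,0.475073485851043,rep3
1.6,0.509945940366735,rep1
1.6,0.513783410065764,rep2
1.6,0.50703947986274,rep3
4.8,0.549855419446309,rep1
4.8,0.534167584055969,rep2
4.8,0.540779155792215,rep3
9.6,0.549336895863758,rep1
9.6,0.54574276546902,rep2
9.6,0.55072188818776,rep3
16,0.549298188312099,rep1
16,0.542568892193145,rep2
16,0.552901899614462,rep3
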