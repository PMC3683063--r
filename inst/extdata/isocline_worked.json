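{"K1":19.9,"K2":21.6,"K_co":21.8,"p1":0.55,"note":"printed dry-weight carrying capacities (g per 30 ml) and co-culture proportion for the worked isocline example"}
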