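genotype,n_pollen,n_recombinant
wild_type,4382,272
atm-2,2723,291
msh4,4038,69
msh4 atm-2,1685,118
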