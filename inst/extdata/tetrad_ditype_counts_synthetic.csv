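experiment,genotype,interval1,interval2,focal,class1,class2,n
I5cd,wild_type,I5c,I5d,I5d,PD,PD,3567
I5cd,wild_type,I5c,I5d,I5d,PD,TT,558
I5cd,wild_type,I5c,I5d,I5d,TT,PD,530
I5cd,wild_type,I5c,I5d,I5d,TT,TT,27
I5cd,atm-2,I5c,I5d,I5d,PD,PD,469
I5cd,atm-2,I5c,I5d,I5d,PD,TT,120
I5cd,atm-2,I5c,I5d,I5d,PD,NPD,1
I5cd,atm-2,I5c,I5d,I5d,TT,PD,80
I5cd,atm-2,I5c,I5d,I5d,TT,TT,25
I5cd,atm-2,I5c,I5d,I5d,TT,NPD,1
I2ab,wild_type,I2a,I2b,I2a,PD,PD,3859
I2ab,wild_type,I2a,I2b,I2a,PD,TT,413
I2ab,wild_type,I2a,I2b,I2a,PD,NPD,1
I2ab,wild_type,I2a,I2b,I2a,TT,PD,264
I2ab,wild_type,I2a,I2b,I2a,TT,TT,5
I2ab,atm-2,I2a,I2b,I2a,PD,PD,406
I2ab,atm-2,I2a,I2b,I2a,PD,TT,50
I2ab,atm-2,I2a,I2b,I2a,PD,NPD,1
I2ab,atm-2,I2a,I2b,I2a,TT,PD,68
I2ab,atm-2,I2a,I2b,I2a,TT,TT,10
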