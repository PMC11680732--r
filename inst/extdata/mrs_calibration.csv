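region,species,t2_ms,t2_sd_ms,conc_mM,conc_sd_mM
striatum,Glu,107,9,6.5,0.3
striatum,tCr,145,12,7.2,0.2
striatum,Ins,188,19,3.4,0.3
striatum,tNAA,243,19,5.3,0.1
striatum,Tau,125,9,12.2,0.7
striatum,water,31.7,0.6,45500,200
corpus_callosum,Glu,99,8,5.7,0.4
corpus_callosum,tCr,159,4,5.8,0.2
corpus_callosum,Ins,129,10,3.3,0.2
corpus_callosum,tNAA,278,20,4.6,0.3
corpus_callosum,Tau,125,6,8.0,0.2
corpus_callosum,water,28.8,1.2,46500,700
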