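sample_id,condition,enzyme,dpm,dna_mass_mg
u1,untreated,HpaII,2080,0.5
u1,untreated,HpaII,2120,0.5
u1,untreated,MspI,5010,0.5
u1,untreated,MspI,4990,0.5
u1,untreated,background,100,0.5
t1,aza_treated,HpaII,3290,0.5
t1,aza_treated,HpaII,3310,0.5
t1,aza_treated,MspI,4995,0.5
t1,aza_treated,MspI,5005,0.5
t1,aza_treated,background,100,0.5
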