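sample_id,condition,well,cell_id,treatment,tail_intensity
u1,untreated,1,1,control,1.0
u1,untreated,1,2,control,2.0
u1,untreated,2,1,control,1.5
u1,untreated,2,2,control,2.5
u1,untreated,1,1,HpaII,18.0
u1,untreated,1,2,HpaII,22.0
u1,untreated,2,1,HpaII,20.0
u1,untreated,2,2,HpaII,21.0
u1,untreated,1,1,MspI,38.0
u1,untreated,1,2,MspI,42.0
u1,untreated,2,1,MspI,40.0
u1,untreated,2,2,MspI,39.0
t1,aza_treated,1,1,control,1.0
t1,aza_treated,1,2,control,1.5
t1,aza_treated,2,1,control,2.0
t1,aza_treated,2,2,control,2.0
t1,aza_treated,1,1,HpaII,26.0
t1,aza_treated,1,2,HpaII,30.0
t1,aza_treated,2,1,HpaII,28.0
t1,aza_treated,2,2,HpaII,27.0
t1,aza_treated,1,1,MspI,41.0
t1,aza_treated,1,2,MspI,39.0
t1,aza_treated,2,1,MspI,40.0
t1,aza_treated,2,2,MspI,42.0
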