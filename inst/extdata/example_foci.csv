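experiment_id,direction,n_subjects,space,x,y,z
smith2010,decrease,24,TAL,-38,-18,8
smith2010,decrease,24,TAL,-4,-40,40
smith2010,decrease,24,TAL,41,-21,43
jones2012,decrease,15,MNI,-40,-16,6
jones2012,decrease,15,MNI,-22,-62,-22
lee2015,increase,31,TAL,31,41,19
lee2015,increase,31,TAL,-29,39,15
lee2015,increase,31,TAL,5,21,-13
garcia2018,increase,12,TAL,17,-79,-27
garcia2018,increase,12,TAL,29,38,22
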