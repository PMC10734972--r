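studlab,treat1,treat2,TE,seTE
1,No active control,Florfenicol,1.817766,0.4198201
2,No active control,Enrofloxacin,3.471966,1.5027924
3,No active control,Enrofloxacin,3.201584,0.4781349
4,No active control,Enrofloxacin,1.434531,0.3878773
5,No active control,Enrofloxacin,3.197472,0.4938823
6,No active control,Enrofloxacin,1.945910,0.3854496
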