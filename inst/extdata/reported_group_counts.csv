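group,n,converted,a_pos,t_pos,n_pos
atn_case,95,68,95,92,67
atn_control,95,5,1,0,0
converter,74,74,69,66,50
nonconverter,117,0,28,27,18
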