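label,tmsf_nm2
P180/S180,0.47
P300/S180,0.64
P180/S300,1.33
P300/S300,2.97
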