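participant,deg2,deg4,deg6,deg8,deg10
S1,25.00,8.33,8.33,8.33,8.33
S2,8.33,0,0,0,0
S3,0,0,0,0,0
S4,8.33,8.33,0,0,0
S5,9.09,9.09,0,0,0
S6,8.33,8.33,0,0,0
S7,25.00,0,0,0,0
S8,8.33,8.33,8.33,8.33,8.33
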