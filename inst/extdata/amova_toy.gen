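toy 3-population microsatellite panel (synthetic)
locA
locB
Pop
t1_i1 , 001002 003003
t1_i2 , 001001 003004
t1_i3 , 002002 004004
Pop
t2_i1 , 002003 003003
t2_i2 , 003003 004005
t2_i3 , 002002 005005
Pop
t3_i1 , 005005 001001
t3_i2 , 005006 001002
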