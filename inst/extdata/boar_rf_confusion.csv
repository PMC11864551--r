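class,RLP,RSP,Foraging,Lactating,Scrubbing,Standing,Walking
RLP,33,0,1,0,0,1,0
RSP,1,62,5,1,0,3,0
Foraging,0,0,1013,0,0,4,0
Lactating,1,2,1,13,0,0,0
Scrubbing,0,0,2,0,0,0,0
Standing,1,2,12,0,0,17,0
Walking,0,0,25,0,0,0,0
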