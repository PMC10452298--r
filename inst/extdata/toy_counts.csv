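species,y,x
x,2,23.4
y,8,26.7
z,12,24.5
u,5,30.6
v,16,32.5
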