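# Reference winter wheat cultivar (baseline for yield-gap analysis)
name = Claire
ph = 110
pp = 0.565
gf = 650
amax = 0.007
sg = 0.5
ru = 3
wss = 1.27
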