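# Michaelis-Menten mechanism, mass action
# x1 = substrate, x2 = complex, x3 = enzyme, x4 = product
init: x1=1
init: x3=0.1
x1 + x3 -> x2 ; k=1
x2 -> x1 + x3 ; k=1
x2 -> x3 + x4 ; k=0.1
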