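2
HF optimized with the native B3LYP(VWN5)/6-311G** engine charge=0 mult=1
F       0.000000000000     0.000000000000     0.000000000000
H       0.000000000000     0.000000000000     0.920473256484
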