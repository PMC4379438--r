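# ceria-like calibrant, fcc a0 = 5.41153 A (standard lattice value)
3.12435
2.70576
1.91326
1.63164
1.56217
1.35288
1.24149
1.21005
1.10462
1.04145
0.95663
0.91472
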