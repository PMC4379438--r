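# LaB6-like calibrant, simple cubic a0 = 4.1566 A (standard lattice value)
# one d-spacing (angstrom) per line
4.15660
2.93916
2.39981
2.07830
1.85889
1.69692
1.46958
1.38553
1.31443
1.25326
1.19991
1.15283
1.11090
1.03915
1.00812
0.97972
0.95359
0.92944
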