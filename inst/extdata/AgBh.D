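# silver-behenate-like SAXS calibrant, lamellar period 58.380 A (standard value)
58.38000
29.19000
19.46000
14.59500
11.67600
9.73000
8.34000
7.29750
6.48667
5.83800
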