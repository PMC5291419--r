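>ets_demo
A [ 12  2  1  0 16 11 ]
C [  3 13  1  1  1  2 ]
G [  2  2 17 18  2  3 ]
T [  3  3  1  1  1  4 ]
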