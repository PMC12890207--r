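tip,trait
A,1
B,2
C,3
D,4
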