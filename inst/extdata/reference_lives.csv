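patient,integration_point,life_cycles
A,top,5.65e9
A,bottom,4.58e9
B,top,4.58e8
B,bottom,2.02e9
C,top,9.30e5
C,bottom,4.40e5
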