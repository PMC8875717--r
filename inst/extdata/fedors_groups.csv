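group,E,V
CH3,4707,33.5
CH2,4937.12,16.1
CH,3430.88,-1.0
C,1464.4,-19.2
COOH,27614.4,28.5
benzene ring,31923.92,33.4
ring,1046,16.0
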