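group,R,Q
CH3,0.9011,0.848
CH2,0.6744,0.540
CH,0.4469,0.228
C,0.2195,0.000
COOH,1.3013,1.224
ACH,0.5313,0.400
AC,0.3652,0.120
ACCH3,1.2663,0.968
ACCH2,1.0396,0.660
ACCH,0.8121,0.348
CH2=CH,1.3454,1.176
CH=CH,1.1167,0.867
CH2=C,1.1173,0.988
CH=C,0.8886,0.676
C=C,0.6605,0.485
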