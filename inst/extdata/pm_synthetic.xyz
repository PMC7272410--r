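6
PM synthetic stand-in (planar S1 minimum analogue)
C       0.000000     0.000000     0.000000
C       1.470000     0.000000     0.000000
C       2.211887    -1.187267     0.000000
C       3.571058    -1.234731    -0.000000
C       4.261182    -2.532664     0.000000
O       5.486501    -2.639865    -0.000000
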