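6
SB synthetic stand-in (single-bond rotated analogue)
C       0.000000     0.000000     0.000000
C       1.470000     0.000000     0.000000
C       2.211887    -1.187267     0.000000
C       2.648262    -1.811358    -1.126804
C       3.478041    -3.020319    -1.022974
O       3.902196    -3.628057    -2.004629
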