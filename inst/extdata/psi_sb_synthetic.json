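{"label":"planar pi-like synthetic stand-in","primitives":[{"centre":[-2.6,0,0],"l":[0,0,1],"alpha":0.6,"coeff":1},{"centre":[0,0,0],"l":[0,0,1],"alpha":0.6,"coeff":-1.3},{"centre":[2.6,0,0],"l":[0,0,1],"alpha":0.6,"coeff":1}]}
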