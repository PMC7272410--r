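{"label":"twisted delocalised synthetic stand-in","primitives":[{"centre":[-1.3,0,0],"l":[0,0,1],"alpha":0.8,"coeff":1},{"centre":[1.3,0,0],"l":[0,1,0],"alpha":0.8,"coeff":1}]}
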