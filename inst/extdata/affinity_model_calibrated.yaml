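window_length: 26
core_length: 15
slide_window: 9
sigma: 0.2
coef:
  intercept: 11.024572305725782
  stop: 0.667306026116703
  slide: 0.648788003027544
  bend: 0.332970925882052
dinucleotide:
  AA: -0.114437025929921
  AC: 0.259108342374589
  AG: -0.012324619113579
  AT: -0.325768106928957
  CA: 0.212245451357462
  CC: -0.011433513006048
  CG: -0.070684853985112
  CT: 0.051795953541645
  GA: -0.044575300943045
  GC: 0.017061220476666
  GG: 0.068388198164399
  GT: 0.063943700082714
  TA: -0.341260967188992
  TC: -0.054243972772527
  TG: 0.151063106707688
  TT: 0.178683817927332
pwm:
  A:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 1.0
  - 0.5
  - 1.0
  - 0.5
  - 0.5
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  C:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  G:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.5
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  T:
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 1.0
  - 0.0
  - 0.5
  - 0.0
  - 0.5
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
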