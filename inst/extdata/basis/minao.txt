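# Basis set: minao
# Published Gaussian basis-set definition (Basis Set Exchange data),
# transcribed as plain text. Format: 'element <sym>', 'shell <l>',
# then one 'exponent coefficient' pair per line.
element H
shell 0
  33.87 0.006068
  5.095 0.045308
  1.159 0.202822
  0.3258 0.503903
  0.1027 0.383421
element He
shell 0
  234 0.002587
  35.16 0.019533
  7.989 0.090998
  2.212 0.27205
  0.6669 0.478065
  0.2089 0.307737
element Li
shell 0
  5988 0.000133
  898.9 0.001025
  205.9 0.005272
  59.24 0.020929
  19.87 0.06634
  7.406 0.165775
  2.93 0.315038
  1.189 0.393523
  0.4798 0.19087
  0.07509 0.005414
  0.02832 -0.001328
shell 0
  5988 -2.1e-05
  898.9 -0.000161
  205.9 -0.00082
  59.24 -0.003326
  19.87 -0.010519
  7.406 -0.028097
  2.93 -0.055936
  1.189 -0.099237
  0.4798 -0.112189
  0.07509 0.567889
  0.02832 0.530382
element C
shell 0
  8236 0.000531
  1235 0.004108
  280.8 0.021087
  79.27 0.081853
  25.59 0.234817
  8.997 0.434401
  3.319 0.346129
  0.9059 0.039378
  0.3643 -0.008983
  0.1285 0.002385
shell 0
  8236 -0.000113
  1235 -0.000878
  280.8 -0.00454
  79.27 -0.018133
  25.59 -0.05576
  8.997 -0.126895
  3.319 -0.170352
  0.9059 0.140382
  0.3643 0.598684
  0.1285 0.395389
shell 1
  18.71 0.014031
  4.133 0.086866
  1.2 0.290216
  0.3827 0.501008
  0.1209 0.343406
element N
shell 0
  11420 0.000523
  1712 0.004045
  389.3 0.020775
  110 0.080727
  35.57 0.233074
  12.54 0.433501
  4.644 0.347472
  1.293 0.041262
  0.5118 -0.008508
  0.1787 0.002384
shell 0
  11420 -0.000115
  1712 -0.000895
  389.3 -0.004624
  110 -0.018528
  35.57 -0.057339
  12.54 -0.132076
  4.644 -0.17251
  1.293 0.151814
  0.5118 0.599944
  0.1787 0.387462
shell 1
  26.63 0.01467
  5.948 0.091764
  1.742 0.298683
  0.555 0.498487
  0.1725 0.337023
element O
shell 0
  15330 0.000508
  2299 0.003929
  522.4 0.020243
  147.3 0.079181
  47.55 0.230687
  16.76 0.433118
  6.207 0.35026
  1.752 0.042728
  0.6882 -0.008154
  0.2384 0.002381
shell 0
  15330 -0.000115
  2299 -0.000895
  522.4 -0.004636
  147.3 -0.018724
  47.55 -0.058463
  16.76 -0.136463
  6.207 -0.17574
  1.752 0.160934
  0.6882 0.603418
  0.2384 0.378765
shell 1
  34.46 0.015928
  7.749 0.09974
  2.28 0.310492
  0.7156 0.491026
  0.214 0.336337
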