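# Basis set: cc-pvdz
# Published Gaussian basis-set definition (Basis Set Exchange data),
# transcribed as plain text. Format: 'element <sym>', 'shell <l>',
# then one 'exponent coefficient' pair per line.
element H
shell 0
  13.01 0.019685
  1.962 0.137977
  0.4446 0.478148
shell 0
  0.122 1
shell 1
  0.727 1
element He
shell 0
  38.36 0.023809
  5.77 0.154891
  1.24 0.469987
shell 0
  0.2976 1
shell 1
  1.275 1
element Li
shell 0
  1469 0.000766
  220.5 0.005892
  50.26 0.029671
  14.24 0.10918
  4.581 0.282789
  1.58 0.453123
  0.564 0.274774
  0.07345 0.009751
shell 0
  1469 -0.00012
  220.5 -0.000923
  50.26 -0.004689
  14.24 -0.017682
  4.581 -0.048902
  1.58 -0.096009
  0.564 -0.13638
  0.07345 0.575102
shell 0
  0.02805 1
shell 1
  1.534 0.022784
  0.2749 0.139107
  0.07362 0.500375
shell 1
  0.02403 1
shell 2
  0.1239 1
element C
shell 0
  6665 0.000692
  1000 0.005329
  228 0.027077
  64.71 0.101718
  21.06 0.27474
  7.495 0.448564
  2.797 0.285074
  0.5215 0.015204
shell 0
  6665 -0.000146
  1000 -0.001154
  228 -0.005725
  64.71 -0.023312
  21.06 -0.063955
  7.495 -0.149981
  2.797 -0.127262
  0.5215 0.544529
shell 0
  0.1596 1
shell 1
  9.439 0.038109
  2.002 0.20948
  0.5456 0.508557
shell 1
  0.1517 1
shell 2
  0.55 1
element N
shell 0
  9046 0.0007
  1357 0.005389
  309.3 0.027406
  87.73 0.103207
  28.56 0.278723
  10.21 0.44854
  3.838 0.278238
  0.7466 0.01544
shell 0
  9046 -0.000153
  1357 -0.001208
  309.3 -0.005992
  87.73 -0.024544
  28.56 -0.067459
  10.21 -0.158078
  3.838 -0.121831
  0.7466 0.549003
shell 0
  0.2248 1
shell 1
  13.55 0.039919
  2.917 0.217169
  0.7973 0.510319
shell 1
  0.2185 1
shell 2
  0.817 1
element O
shell 0
  11720 0.00071
  1759 0.00547
  400.8 0.027837
  113.7 0.1048
  37.03 0.283062
  13.27 0.448719
  5.025 0.270952
  1.013 0.015458
shell 0
  11720 -0.00016
  1759 -0.001263
  400.8 -0.006267
  113.7 -0.025716
  37.03 -0.070924
  13.27 -0.165411
  5.025 -0.116955
  1.013 0.557368
shell 0
  0.3023 1
shell 1
  17.7 0.043018
  3.854 0.228913
  1.046 0.508728
shell 1
  0.2753 1
shell 2
  1.185 1
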