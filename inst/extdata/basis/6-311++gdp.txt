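# Basis set: 6-311++g(d,p)
# Published Gaussian basis-set definition (Basis Set Exchange data),
# transcribed as plain text. Format: 'element <sym>', 'shell <l>',
# then one 'exponent coefficient' pair per line.
element H
shell 0
  33.865 0.0254938
  5.09479 0.190373
  1.15879 0.852161
shell 0
  0.32584 1
shell 0
  0.102741 1
shell 0
  0.036 1
shell 1
  0.75 1
element C
shell 0
  4563.24 0.00196665
  682.024 0.0152306
  154.973 0.0761269
  44.4553 0.260801
  13.029 0.616462
  1.82773 0.221006
shell 0
  20.9642 0.11466
  4.80331 0.919999
  1.45933 -0.00303068
shell 0
  0.483456 1
shell 0
  0.145585 1
shell 0
  0.0438 1
shell 1
  20.9642 0.0402487
  4.80331 0.237594
  1.45933 0.815854
shell 1
  0.483456 1
shell 1
  0.145585 1
shell 1
  0.0438 1
shell 2
  0.626 1
element N
shell 0
  6293.48 0.00196979
  949.044 0.0149613
  218.776 0.0735006
  63.6916 0.248937
  18.8282 0.60246
  2.72023 0.256202
shell 0
  30.6331 0.111906
  7.02614 0.921666
  2.11205 -0.00256919
shell 0
  0.684009 1
shell 0
  0.200878 1
shell 0
  0.0639 1
shell 1
  30.6331 0.0383119
  7.02614 0.237403
  2.11205 0.817592
shell 1
  0.684009 1
shell 1
  0.200878 1
shell 1
  0.0639 1
shell 2
  0.913 1
element O
shell 0
  8588.5 0.00189515
  1297.23 0.0143859
  299.296 0.070732
  87.3771 0.240001
  25.6789 0.594797
  3.74004 0.280802
shell 0
  42.1175 0.113889
  9.62837 0.920811
  2.85332 -0.00327447
shell 0
  0.905661 1
shell 0
  0.255611 1
shell 0
  0.0845 1
shell 1
  42.1175 0.0365114
  9.62837 0.237153
  2.85332 0.819702
shell 1
  0.905661 1
shell 1
  0.255611 1
shell 1
  0.0845 1
shell 2
  1.292 1
element Li
shell 0
  900.46 0.00228704
  134.433 0.017635
  30.4365 0.0873434
  8.62639 0.280977
  2.48332 0.658741
  0.303179 0.118712
shell 0
  4.8689 0.0933293
  0.856924 0.943045
  0.243227 -0.00279827
shell 0
  0.063507 1
shell 0
  0.0243683 1
shell 0
  0.0074 1
shell 1
  4.8689 0.0327661
  0.856924 0.159792
  0.243227 0.885667
shell 1
  0.063507 1
shell 1
  0.0243683 1
shell 1
  0.0074 1
shell 2
  0.2 1
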