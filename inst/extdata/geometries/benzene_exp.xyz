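12
experimental equilibrium geometry (NIST CCCBDB): rCC 1.3964, rCH 1.083, D6h
C 1.396400 0.000000 0.000000
H 2.479400 0.000000 0.000000
C 0.698200 1.209318 0.000000
H 1.239700 2.147223 0.000000
C -0.698200 1.209318 0.000000
H -1.239700 2.147223 0.000000
C -1.396400 0.000000 0.000000
H -2.479400 0.000000 0.000000
C -0.698200 -1.209318 0.000000
H -1.239700 -2.147223 0.000000
C 0.698200 -1.209318 0.000000
H 1.239700 -2.147223 0.000000
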