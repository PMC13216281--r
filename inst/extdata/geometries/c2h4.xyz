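6
experimental equilibrium geometry (NIST CCCBDB): rCC 1.339, rCH 1.086, HCH 117.6 deg
C 0.000000 0.000000 0.669500
C 0.000000 0.000000 -0.669500
H 0.928926 0.000000 1.232077
H -0.928926 0.000000 1.232077
H 0.928926 0.000000 -1.232077
H -0.928926 0.000000 -1.232077
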