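5
experimental equilibrium geometry, r(C-H) = 1.087 A (NIST CCCBDB)
C 0.000000 0.000000 0.000000
H 0.627580 0.627580 0.627580
H 0.627580 -0.627580 -0.627580
H -0.627580 0.627580 -0.627580
H -0.627580 -0.627580 0.627580
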