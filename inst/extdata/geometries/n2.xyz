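2
experimental equilibrium geometry, r(N-N) = 1.0977 A (NIST CCCBDB)
N 0.000000 0.000000 0.000000
N 0.000000 0.000000 1.097700
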