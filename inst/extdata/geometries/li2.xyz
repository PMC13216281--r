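2
experimental equilibrium geometry, r(Li-Li) = 2.673 A (NIST CCCBDB)
Li 0.000000 0.000000 0.000000
Li 0.000000 0.000000 2.673000
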