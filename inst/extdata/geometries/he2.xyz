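2
van der Waals dimer, r(He-He) = 2.97 A (5.61 bohr)
He 0.000000 0.000000 0.000000
He 0.000000 0.000000 2.970000
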