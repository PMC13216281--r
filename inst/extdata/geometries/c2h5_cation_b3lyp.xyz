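7
synthetic reference: non-classical bridged structure optimized at B3LYP/6-311++G(d,p) (pyscf 2.12 + geomeTRIC, this work); charge +1
C -0.690216 -0.277076 -0.000061
C 0.690216 -0.277076 -0.000061
H 0.000000 0.851177 -0.000209
H -1.246631 -0.287258 0.934518
H -1.246756 -0.287274 -0.934570
H 1.246631 -0.287258 0.934518
H 1.246756 -0.287274 -0.934570
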