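18
synthetic reference: chair, optimized at B3LYP/6-311++G(d,p) (pyscf 2.12 + geomeTRIC, this work)
C 1.466358 -0.000000 0.230648
H 1.535715 -0.000000 1.326590
H 2.494870 -0.000000 -0.145217
C 0.733734 1.270279 -0.227123
H 0.771064 1.331964 -1.322889
H 1.247095 2.160431 0.151302
C -0.733734 1.270279 0.227123
H -0.771064 1.331964 1.322889
H -1.247095 2.160431 -0.151302
C -1.466358 -0.000000 -0.230648
H -1.535715 -0.000000 -1.326590
H -2.494870 -0.000000 0.145217
C -0.733734 -1.270279 0.227123
H -0.771064 -1.331964 1.322889
H -1.247095 -2.160431 -0.151302
C 0.733734 -1.270279 -0.227123
H 0.771064 -1.331964 -1.322889
H 1.247095 -2.160431 0.151302
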