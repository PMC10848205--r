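strain	flow_rate	replicate	collected	injected
A68	0.5	1	2.31e8	3.3e8
A68	0.5	2	2.26e8	3.3e8
A68	0.5	3	2.34e8	3.3e8
A68	1	1	2.28e8	3.3e8
A68	1	2	2.33e8	3.3e8
A68	1	3	2.30e8	3.3e8
A68	2	1	2.30e8	3.3e8
A68	2	2	2.25e8	3.3e8
A68	2	3	2.35e8	3.3e8
A3	0.5	1	9.5e7	3.3e8
A3	0.5	2	9.9e7	3.3e8
A3	0.5	3	9.6e7	3.3e8
A3	1	1	9.8e7	3.3e8
A3	1	2	9.4e7	3.3e8
A3	1	3	1.01e8	3.3e8
A3	2	1	9.7e7	3.3e8
A3	2	2	9.2e7	3.3e8
A3	2	3	1.02e8	3.3e8
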