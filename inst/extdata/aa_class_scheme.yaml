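# Default chemical-class partition of the 20 standard amino acids.
# Histidine sits with the polar residues. Edit and pass to
# read_class_scheme() to use a different partition.
hydrophobic: [A, V, L, I, M, F, W]
non-polar: [G, P, C]
polar: [S, T, Y, N, Q, H]
basic: [K, R]
acidic: [D, E]
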