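>SYN0001.1 synthetic_ctcf_like_19bp (constructed stand-in motif, 19 columns; not the JASPAR MA0139.1 matrix)
A [   4   2   3  94   2   3  94   2   4   2   6   3   2   2  92   4   3   6  30 ]
C [  88   4  90   2  92   4   2  90  88   4   5  90   3   4   3  86   6   8  28 ]
G [   5  90   4   2   3  89   2   4   4  90  85   4   3  88   3   6  87  10  24 ]
T [   3   4   3   2   3   4   2   4   4   4   4   3  92   6   2   4   4  76  18 ]
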