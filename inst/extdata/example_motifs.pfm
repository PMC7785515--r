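>AP1_like bZIP dimer consensus TGACTCAT
A [  0  0 50  0  0  0 50  0 ]
C [  0  0  0 50  0 50  0  0 ]
G [  0 50  0  0  0  0  0  0 ]
T [ 50  0  0  0 50  0  0 50 ]
>NFKB_like rel homology consensus GGGACTTTCC
A [  0  0  0 40  0  5  5  0  0  0 ]
C [  5  0  0  5 35  5  5  5 40 40 ]
G [ 35 40 40  0  0  0  0  0  0  0 ]
T [  0  0  0  0  5 30 30 35  0  0 ]
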