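>IRF1_like IRF1_like_synthetic
A  [  5  3 90  2  8  4  2  6  4  3 ]
C  [  4  2  3  3  4 88  3  2  5 89 ]
G  [  3  4  4  2  5  4  3  4  3  4 ]
T  [ 88 91  3 93 83  4 92 88 88  4 ]
>SMAD3_like SMAD3_like_synthetic
A  [  4  3  2  5 90  3 92  4 ]
C  [  3  4 89  4  3  2  3 88 ]
G  [ 89  4  4  3  4 91  2  4 ]
T  [  4 89  5 88  3  4  3  4 ]
>JUN_like JUN_like_synthetic
A  [  5 84  3  4  6 88  5 ]
C  [  4  5  4 87  5  3  5 ]
G  [  3  6 89  4  5  4  4 ]
T  [ 88  5  4  5 84  5 86 ]
>JUND_like JUND_like_synthetic
A  [  4 86  4  3 87  4  5 ]
C  [  5  4  3  5  4  4 88 ]
G  [  4  5 88  4  4  5  3 ]
T  [ 87  5  5 88  5 87  4 ]
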