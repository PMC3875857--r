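>Reb1
0.030 0.030 0.030 0.910
0.030 0.030 0.030 0.910
0.910 0.030 0.030 0.030
0.030 0.910 0.030 0.030
0.030 0.910 0.030 0.030
0.030 0.910 0.030 0.030
0.030 0.030 0.910 0.030
>Abf1
0.455 0.045 0.455 0.045
0.030 0.030 0.030 0.910
0.030 0.910 0.030 0.030
0.910 0.030 0.030 0.030
0.030 0.910 0.030 0.030
0.030 0.030 0.910 0.030
0.030 0.030 0.030 0.910
>Rap1
0.910 0.030 0.030 0.030
0.030 0.910 0.030 0.030
0.910 0.030 0.030 0.030
0.030 0.910 0.030 0.030
0.030 0.910 0.030 0.030
0.030 0.910 0.030 0.030
0.910 0.030 0.030 0.030
0.030 0.030 0.030 0.910
0.910 0.030 0.030 0.030
>Rsc3
0.030 0.910 0.030 0.030
0.030 0.030 0.910 0.030
0.030 0.910 0.030 0.030
0.030 0.030 0.910 0.030
0.030 0.910 0.030 0.030
>TATA
0.030 0.030 0.030 0.910
0.910 0.030 0.030 0.030
0.030 0.030 0.030 0.910
0.910 0.030 0.030 0.030
0.455 0.045 0.045 0.455
0.910 0.030 0.030 0.030
0.455 0.045 0.045 0.455
0.455 0.045 0.455 0.045
>Hrp1
0.030 0.030 0.030 0.910
0.910 0.030 0.030 0.030
0.030 0.030 0.030 0.910
0.910 0.030 0.030 0.030
0.030 0.030 0.030 0.910
0.910 0.030 0.030 0.030
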