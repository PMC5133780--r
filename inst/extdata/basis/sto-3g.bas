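! STO-3G minimal basis (Hehre-Stewart-Pople least-squares STO expansions).
ELEMENT H
S 3
   3.42525091  0.15432897
   0.62391373  0.53532814
   0.16885540  0.44463454
END
ELEMENT C
S 3
  71.61683700  0.15432897
  13.04509600  0.53532814
   3.53051220  0.44463454
S 3
   2.94124940 -0.09996723
   0.68348310  0.39951283
   0.22228990  0.70011547
P 3
   2.94124940  0.15591627
   0.68348310  0.60768372
   0.22228990  0.39195739
END
ELEMENT N
S 3
  99.10616900  0.15432897
  18.05231200  0.53532814
   4.88566020  0.44463454
S 3
   3.78045590 -0.09996723
   0.87849660  0.39951283
   0.28571440  0.70011547
P 3
   3.78045590  0.15591627
   0.87849660  0.60768372
   0.28571440  0.39195739
END
ELEMENT O
S 3
 130.70932000  0.15432897
  23.80886100  0.53532814
   6.44360830  0.44463454
S 3
   5.03315130 -0.09996723
   1.16959610  0.39951283
   0.38038900  0.70011547
P 3
   5.03315130  0.15591627
   1.16959610  0.60768372
   0.38038900  0.39195739
END
ELEMENT F
S 3
 166.67913400  0.15432897
  30.36081233  0.53532814
   8.21682067  0.44463454
S 3
   6.46480325 -0.09996723
   1.50228124  0.39951283
   0.48858849  0.70011547
P 3
   6.46480325  0.15591627
   1.50228124  0.60768372
   0.48858849  0.39195739
END
ELEMENT Cl
S 3
 601.34561130  0.15432897
 109.53585420  0.53532814
  29.64467686  0.44463454
S 3
  38.96041889 -0.09996723
   9.04595042  0.39951283
   2.94449983  0.70011547
P 3
  38.96041889  0.15591627
   9.04595042  0.60768372
   2.94449983  0.39195739
S 3
   2.12938650 -0.21962037
   0.59409343  0.22559543
   0.23252414  0.90039843
P 3
   2.12938650  0.01058760
   0.59409343  0.59516701
   0.23252414  0.46200101
END
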