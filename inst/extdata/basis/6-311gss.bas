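! 6-311G** triple-split-valence basis with polarization functions.
! Transcribed from the standard published tabulations (Krishnan et al.
! 6-311G for H,C,N,O,F; Cl carried as an uncontracted (12s,9p) set of the standard
! triple-split exponents) with the
! usual polarization exponents (H p 0.75; C d 0.626; N d 0.913;
! O d 1.292; F d 1.75; Cl d 0.75).
ELEMENT H
S 3
  33.865000   0.02549380
   5.094790   0.19037300
   1.158790   0.85216100
S 1
   0.325840   1.0
S 1
   0.102741   1.0
P 1
   0.750000   1.0
END
ELEMENT C
S 6
  4563.240000  0.00196665
   682.024000  0.01523060
   154.973000  0.07612690
    44.455300  0.26080100
    13.029000  0.61646200
     1.827730  0.22100600
S 3
    20.964200  0.11466000
     4.803310  0.91999900
     1.459330 -0.00303068
S 1
     0.483456  1.0
S 1
     0.145585  1.0
P 3
    20.964200  0.04024870
     4.803310  0.23759400
     1.459330  0.81585400
P 1
     0.483456  1.0
P 1
     0.145585  1.0
D 1
     0.626000  1.0
END
ELEMENT N
S 6
  6293.480000  0.00196979
   949.044000  0.01496130
   218.776000  0.07350060
    63.691600  0.24893700
    18.828200  0.60246000
     2.720230  0.25620200
S 3
    30.633100  0.11190600
     7.026140  0.92166600
     2.112050 -0.00256919
S 1
     0.684009  1.0
S 1
     0.200878  1.0
P 3
    30.633100  0.03831190
     7.026140  0.23740300
     2.112050  0.81759200
P 1
     0.684009  1.0
P 1
     0.200878  1.0
D 1
     0.913000  1.0
END
ELEMENT O
S 6
  8588.500000  0.00189515
  1297.230000  0.01438590
   299.296000  0.07073200
    87.377100  0.24000100
    25.678900  0.59479700
     3.740040  0.28080200
S 3
    42.117500  0.11388900
     9.628370  0.92081100
     2.853320 -0.00327447
S 1
     0.905661  1.0
S 1
     0.255611  1.0
P 3
    42.117500  0.03651140
     9.628370  0.23715300
     2.853320  0.81970200
P 1
     0.905661  1.0
P 1
     0.255611  1.0
D 1
     1.292000  1.0
END
ELEMENT F
S 6
 11427.100000  0.00180093
  1722.350000  0.01374190
   395.746000  0.06813340
   115.139000  0.23332500
    33.602600  0.58908600
     4.919010  0.29950500
S 3
    55.444100  0.11453600
    12.632300  0.92051200
     3.717560 -0.00337804
S 1
     1.165450  1.0
S 1
     0.321892  1.0
P 3
    55.444100  0.03546090
    12.632300  0.23745100
     3.717560  0.82045800
P 1
     1.165450  1.0
P 1
     0.321892  1.0
D 1
     1.750000  1.0
END
ELEMENT Cl
S 1
  105819.000000  1.0
S 1
  15872.000000  1.0
S 1
  3619.650000  1.0
S 1
  1030.800000  1.0
S 1
  339.908000  1.0
S 1
  124.538000  1.0
S 1
  49.513500  1.0
S 1
  20.805600  1.0
S 1
  6.583460  1.0
S 1
  2.564680  1.0
S 1
  0.559763  1.0
S 1
  0.183273  1.0
P 1
  589.776000  1.0
P 1
  139.849000  1.0
P 1
  44.794500  1.0
P 1
  16.611500  1.0
P 1
  6.599360  1.0
P 1
  2.714600  1.0
P 1
  0.952285  1.0
P 1
  0.358281  1.0
P 1
  0.124994  1.0
D 1
      0.750000  1.0
END
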