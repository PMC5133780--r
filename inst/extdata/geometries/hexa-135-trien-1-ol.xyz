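15
hexa-1,3,5-trien-1-ol, MMFF94-optimized, symmetrized to exact planarity charge=0 mult=1
O       1.077740000001    -0.102530579095     0.127449823582
C       2.446200000000    -0.094270167531     0.100339948963
C       3.169329999999    -0.421328943098     1.173920321979
C       4.615470000002    -0.427502131992     1.194189350502
C       5.321219999998    -0.760117908469     2.286010637172
C       6.765249999997    -0.770117737626     2.318840689218
C       7.468090000003    -1.102132532190     3.408689228584
H       0.753040000006     0.165035054691    -0.750841506558
H       2.862019999997     0.196832440770    -0.855209256434
H       2.646550000001    -0.699450864721     2.086859736568
H       5.126989999995    -0.147805639018     0.276081328546
H       4.804350000001    -1.039220696022     3.202169787961
H       7.298789999994    -0.493884698958     1.412101614929
H       6.991850000001    -1.386420736285     4.341869775695
H       8.553539999997    -1.095667246802     3.387470838745
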