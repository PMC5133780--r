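21
hexan-1-ol, MMFF94-optimized (openbabel --gen3d) charge=0 mult=1
O       0.868830000000     0.018560000000     0.011530000000
C       2.289230000000     0.052340000000     0.022930000000
C       2.817450000000    -1.314040000000    -0.390090000000
C       4.344110000000    -1.347820000000    -0.399730000000
C       4.867660000000    -2.723360000000    -0.815080000000
C       6.395680000000    -2.756840000000    -0.824810000000
C       6.919580000000    -4.123250000000    -1.236800000000
H       0.560620000000     0.901420000000     0.278140000000
H       2.623270000000     0.311250000000     1.032710000000
H       2.624690000000     0.827560000000    -0.673300000000
H       2.425390000000    -1.570310000000    -1.382330000000
H       2.424650000000    -2.077110000000     0.293490000000
H       4.723320000000    -1.096450000000     0.598230000000
H       4.723960000000    -0.585960000000    -1.091300000000
H       4.488320000000    -2.975050000000    -1.813020000000
H       4.487880000000    -3.485360000000    -0.123520000000
H       6.780180000000    -2.509690000000     0.171570000000
H       6.780540000000    -1.999960000000    -1.518160000000
H       6.578710000000    -4.899200000000    -0.544050000000
H       8.014060000000    -4.125200000000    -1.237380000000
H       6.578820000000    -4.386860000000    -2.243180000000
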