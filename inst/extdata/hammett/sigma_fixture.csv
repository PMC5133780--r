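substituent,position,sigma,note
H,none,0.00,illustrative fixture values only - not a curated compilation
CH3,meta,-0.07,illustrative fixture values only - not a curated compilation
CH3,para,-0.17,illustrative fixture values only - not a curated compilation
OCH3,meta,0.12,illustrative fixture values only - not a curated compilation
OCH3,para,-0.27,illustrative fixture values only - not a curated compilation
F,meta,0.34,illustrative fixture values only - not a curated compilation
F,para,0.06,illustrative fixture values only - not a curated compilation
Cl,meta,0.37,illustrative fixture values only - not a curated compilation
Cl,para,0.23,illustrative fixture values only - not a curated compilation
CN,meta,0.56,illustrative fixture values only - not a curated compilation
CN,para,0.66,illustrative fixture values only - not a curated compilation
NO2,meta,0.71,illustrative fixture values only - not a curated compilation
NO2,para,0.78,illustrative fixture values only - not a curated compilation
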