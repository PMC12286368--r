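element,authority,limit_mg_kg
Fe,example-WHO-FAO,15
Zn,example-WHO-FAO,25
Cu,example-WHO-FAO,10
Co,example-WHO-FAO,0.1
Cr,example-WHO-FAO,0.1
V,example-WHO-FAO,0.5
Al,example-WHO-FAO,1.0
Ni,example-WHO-FAO,0.8
As,example-WHO-FAO,0.1
Hg,example-WHO-FAO,0.03
Pb,example-WHO-FAO,0.2
Cd,example-WHO-FAO,0.05
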