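region,cohort,element,hq
South,adult,Al,0.029
South,adult,As,5.21
South,adult,Cd,0.170
South,adult,Co,1.297
South,adult,Cr,0.0006
South,adult,Cu,0.283
South,adult,Fe,0.428
South,adult,Ni,0.029
South,adult,Zn,0.192
South,adult,V,0.006
South,child,Al,0.036
South,child,As,6.5135
South,child,Cd,0.213
South,child,Co,0.833
South,child,Cr,0.0008
South,child,Cu,0.354
South,child,Fe,0.535
South,child,Ni,0.036
South,child,Zn,0.239
South,child,V,0.007
East,adult,Al,0.037
East,adult,As,5.066
East,adult,Cd,0.150
East,adult,Co,0.671
East,adult,Cr,0.001
East,adult,Cu,0.300
East,adult,Fe,0.360
East,adult,Ni,0.043
East,adult,Zn,0.201
East,adult,V,0.025
East,child,Al,0.045
East,child,As,6.33
East,child,Cd,0.188
East,child,Co,0.839
East,child,Cr,0.001
East,child,Cu,0.375
East,child,Fe,0.450
East,child,Ni,0.053
East,child,Zn,0.252
East,child,V,0.032
North,adult,Al,0.029
North,adult,As,3.955
North,adult,Cd,0.121
North,adult,Co,0.217
North,adult,Cr,0.001
North,adult,Cu,0.331
North,adult,Fe,0.367
North,adult,Ni,0.032
North,adult,Zn,0.171
North,adult,V,0.004
North,child,Al,0.036
North,child,As,4.943
North,child,Cd,0.152
North,child,Co,0.271
North,child,Cr,0.001
North,child,Cu,0.414
North,child,Fe,0.458
North,child,Ni,0.040
North,child,Zn,0.213
North,child,V,0.005
West,adult,Al,0.034
West,adult,As,4.633
West,adult,Cd,0.157
West,adult,Co,0.276
West,adult,Cr,0.001
West,adult,Cu,0.370
West,adult,Fe,0.383
West,adult,Ni,0.019
West,adult,Zn,0.184
West,adult,V,0.087
West,child,Al,0.041
West,child,As,5.792
West,child,Cd,0.197
West,child,Co,0.345
West,child,Cr,0.002
West,child,Cu,0.463
West,child,Fe,0.479
West,child,Ni,0.024
West,child,Zn,0.230
West,child,V,0.108
Center,adult,Al,0.033
Center,adult,As,5.361
Center,adult,Cd,0.183
Center,adult,Co,0.205
Center,adult,Cr,0.002
Center,adult,Cu,0.380
Center,adult,Fe,0.505
Center,adult,Ni,0.059
Center,adult,Zn,0.192
Center,adult,V,0.047
Center,child,Al,0.041
Center,child,As,6.702
Center,child,Cd,0.229
Center,child,Co,0.256
Center,child,Cr,0.002
Center,child,Cu,0.476
Center,child,Fe,0.613
Center,child,Ni,0.074
Center,child,Zn,0.240
Center,child,V,0.058
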