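region,cohort,element,cr,cr_sd
South,adult,As,4.69e-3,7.24e-4
South,adult,Cd,6.47e-5,2.90e-5
South,child,As,5.86e-3,9.04e-4
South,child,Cd,7.46e-5,3.35e-5
East,adult,As,4.56e-3,6.92e-5
East,adult,Cd,6.47e-5,2.06e-5
East,child,As,5.70e-3,8.65e-4
East,child,Cd,6.85e-5,2.37e-5
North,adult,As,3.56e-3,1.63e-3
North,adult,Cd,4.61e-5,3.68e-5
North,child,As,4.45e-3,2.03e-3
North,child,Cd,5.31e-5,4.23e-5
West,adult,As,4.71e-3,9.96e-4
West,adult,Cd,5.98e-5,2.15e-5
West,child,As,5.21e-3,1.25e-3
West,child,Cd,6.88e-5,2.48e-5
Center,adult,As,4.83e-3,9.10e-4
Center,adult,Cd,6.95e-5,1.72e-5
Center,child,As,6.03e-3,2.90e-5
Center,child,Cd,8.01e-5,1.99e-5
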