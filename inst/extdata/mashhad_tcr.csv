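region,cohort,tcr,tcr_sd
South,adult,4.76e-3,7.53e-4
South,child,5.94e-3,9.38e-4
East,adult,4.62e-3,8.98e-5
East,child,5.77e-3,8.98e-4
North,adult,3.61e-3,1.67e-3
North,child,4.50e-3,2.07e-3
West,adult,4.23e-3,1.02e-3
West,child,5.28e-3,1.27e-3
Center,adult,4.90e-3,9.27e-4
Center,child,6.11e-3,4.89e-5
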