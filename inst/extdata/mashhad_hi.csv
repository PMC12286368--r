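region,cohort,hi
South,adult,7.6446
South,child,8.7673
East,adult,6.854
East,child,8.565
North,adult,5.228
North,child,6.533
West,adult,6.144
West,child,7.681
Center,adult,6.967
Center,child,8.691
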