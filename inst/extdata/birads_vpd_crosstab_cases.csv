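birads,vpd_fatty,vpd_scattered,vpd_heterogeneous,vpd_dense
fatty,59,16,1,0
scattered,50,101,35,3
heterogeneous,5,36,93,29
dense,0,0,7,39
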