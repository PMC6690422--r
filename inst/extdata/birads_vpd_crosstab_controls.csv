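birads,vpd_fatty,vpd_scattered,vpd_heterogeneous,vpd_dense
fatty,388,98,6,0
scattered,217,445,208,8
heterogeneous,4,116,434,124
dense,0,2,32,161
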