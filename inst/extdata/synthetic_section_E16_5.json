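{"outer":"synthetic_section_E16_5_outer.csv","inner":"synthetic_section_E16_5_inner.csv","base":{"x_um":[566.071428571429,-566.071428571429],"y_um":[0,6.9323756308877e-14]},"ac_positions_um":[288.392625721642,854.945372406199,1421.49811909076],"ac_positions_outer_um":[299.311787302011,886.962361293241,1474.61293528447],"stage":16.5}
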