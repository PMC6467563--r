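{"generator":"section","epsilon":0.3,"r0":400,"q":6,"t0":25,"At":12.5,"at_over_t0":0.5,"fold_count":3,"ac_theta":[0.533477997779399,1.580675548976,2.62787310017259],"boundary_noise_sd":0,"n_points":160,"seed":42,"attempt":1}
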