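sample_id	sizes
vkorc1_XX	119,284
vkorc1_XY	119,208,284
vkorc1_YY	208,284
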