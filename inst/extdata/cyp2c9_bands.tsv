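sample_id	sizes
cyp2c9_XX	125,287
cyp2c9_XY	125,200,287
cyp2c9_YY	200,287
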