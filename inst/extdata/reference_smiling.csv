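h9,a1,a3,a4
0.8914,0.3981,0.0503,0.9817
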