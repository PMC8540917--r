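h9,a1,a3,a4
0.8199,0.4270,0.0901,1.0431
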