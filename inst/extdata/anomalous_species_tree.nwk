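((((A:0.5,B:0.5):0.025,C:0.525):0.025,D:0.55):1,E:1.55);
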