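((o1,(o2,o3)),(p1,(f1,(f2,(f3,f4)))));
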