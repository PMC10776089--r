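{"am1":0.5,"am2":0.45,"am3":0.45,"sb1":0.1,"sb2":-0.05,"sb3":-0.05}
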