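ex0001	M
ex0002	M
ex0003	F
ex0004	F
ex0005	M
ex0006	F
ex0007	F
ex0008	F
ex0009	M
ex0010	M
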