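# TOY5: 11-node, 5-level example taxonomy
root	-
A	root
B	root
A1	A
A2a	A
A1a	A1
A1b	A1
A1a1	A1a
A1a2	A1a
B1	B
B1a	B1
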