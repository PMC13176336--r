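material	males	females
ivory	3	5
bone	1	6
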