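# Code stubs: case-sensitive prefixes of the code field.
H33
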