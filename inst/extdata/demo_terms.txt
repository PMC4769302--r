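# Illustrative word-stub term file (one term per line).
# Word stubs match anywhere in the description; "_" builds phrases,
# "+" requires several stubs in one description, "$" excludes.
angin
alcohol+depend
ischemic_cardiomyopathy
splen
$hypersplenism
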