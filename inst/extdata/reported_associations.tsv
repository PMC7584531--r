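# mtDNA variants previously reported to associate with LHON (MITOMAP-style
# association list used for reported-association flagging).
variant	annotation	disease
m.3497C>T	reported/secondary	LHON
m.8836A>G	reported	LHON
m.14831G>A	reported	LHON
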