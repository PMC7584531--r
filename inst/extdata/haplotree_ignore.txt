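# Hypervariable / hotspot positions excluded from haplogroup scoring
309
310
523
524
16182
16183
16519
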