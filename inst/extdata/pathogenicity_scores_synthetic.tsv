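# SYNTHETIC pathogenicity-score table for non-synonymous mtDNA variants,
# scores in [0,1] (MutPred-style; >0.5 treated as likely deleterious).
# Invented values; real analyses should supply a table from an external
# predictor. Scores may be keyed by nucleotide variant, amino-acid change,
# or both.
variant	protein_change	score
m.3497C>T	p.Ala64Val	0.63
m.5460G>A	p.Ala331Thr	0.44
m.8836A>G	p.Met104Val	0.52
m.9055G>A	p.Ala177Thr	0.41
m.11778G>A	p.Arg340His	0.85
m.14831G>A	p.Ala29Thr	0.47
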