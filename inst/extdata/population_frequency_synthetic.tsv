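# SYNTHETIC population-frequency table (percent of GenBank full-length human
# mtDNA sequences carrying the allele). Stand-in for a MITOMAP-style snapshot,
# which is version-dependent and not redistributed. The three reported-
# association variants carry their published GenBank frequencies; marker
# frequencies are invented but plausible for a European population.
variant	percent
m.73A>G	76.0
m.295C>T	9.0
m.709G>A	12.0
m.827A>G	2.5
m.1243T>C	1.8
m.1719G>A	2.4
m.2706A>G	75.0
m.3480A>G	2.3
m.3497C>T	0.35
m.4216T>C	17.0
m.4580G>A	3.5
m.5460G>A	4.2
m.6221T>C	1.9
m.6371C>T	1.9
m.7028C>T	75.0
m.8836A>G	0.28
m.8994G>A	2.0
m.9055G>A	2.1
m.10034T>C	2.2
m.10550A>G	6.6
m.11251A>G	17.0
m.11299T>C	6.5
m.11467A>G	21.0
m.11719G>A	72.0
m.11778G>A	0.26
m.12308A>G	21.0
m.12372G>A	21.0
m.12612A>G	9.0
m.13368G>A	8.0
m.13708G>A	10.0
m.14167C>T	2.0
m.14470T>C	2.1
m.14831G>A	0.20
m.15607A>G	8.0
m.16129G>A	12.0
m.16189T>C	13.0
m.16224T>C	7.0
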