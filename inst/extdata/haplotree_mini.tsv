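# Coarse mtDNA haplogroup scoring tree, rooted at the rCRS baseline (H).
# Each node lists its own defining variants as rCRS-relative derived alleles;
# a node's full defining set is the union along the root-to-node path.
# 'report' is the reporting-level label used for cohort summaries.
name	parent	defining_variants	report
H		 	H
HV	H	m.2706A>G,m.7028C>T	HV
V	HV	m.4580G>A	V
N	HV	m.73A>G,m.11719G>A	N
I	N	m.1719G>A,m.10034T>C,m.16129G>A	I
W	N	m.1243T>C,m.5460G>A,m.8994G>A	W
X	N	m.6221T>C,m.6371C>T,m.14470T>C	X
B	N	m.827A>G,m.16189T>C	B
JT	N	m.4216T>C,m.11251A>G	T
J	JT	m.295C>T,m.12612A>G,m.13708G>A	J
T	JT	m.709G>A,m.13368G>A,m.15607A>G	T
U	N	m.11467A>G,m.12308A>G,m.12372G>A	U
U8	U	m.3480A>G	U
U8b	U8	m.9055G>A,m.14167C>T	U
K	U8b	m.10550A>G,m.11299T>C,m.16224T>C	K
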