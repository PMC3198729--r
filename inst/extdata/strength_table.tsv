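# Ordinal disruption scores for ordered target:guide RNA pairs. Editorial ranking consistent with published single-mismatch allele-discrimination data (G:U wobble weakest non-canonical; C:C more disruptive than A:C and U:C; purine:purine strongest, G:G maximal); not measured free energies.
pair	score
A:U	0
U:A	0
G:C	0
C:G	0
G:U	1
U:G	1
A:C	2
C:A	2
U:C	2
C:U	2
U:U	3
C:C	4
A:G	4
G:A	4
A:A	4
G:G	5
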