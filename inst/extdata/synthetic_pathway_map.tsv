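metabolite	pathway
Dopamine	Dopaminergic synapse
L-DOPA	Dopaminergic synapse
Homovanillic acid	Dopaminergic synapse
3-Methoxytyramine	Dopaminergic synapse
L-Tyrosine	Isoquinoline alkaloid biosynthesis
Dopamine	Isoquinoline alkaloid biosynthesis
4-Hydroxyphenylacetaldehyde	Isoquinoline alkaloid biosynthesis
L-DOPA	Betalain biosynthesis
L-Tyrosine	Betalain biosynthesis
Betanidin	Betalain biosynthesis
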