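metabolite	S001	S002	S003	S004	S005	S006
Dopamine	1.8	2.1	1.2	0.7	0.6	0.9
L-DOPA	0.9	1.1	1.0	0.5	0.4	0.6
Homovanillic acid	2.4	2.0	2.2	1.6	1.5	1.8
L-Tyrosine	5.1	4.8	5.6	5.2	4.9	5.4
2-Hydroxybutyric acid	0.8	0.7	0.9	1.6	1.9	1.7
Methionine sulfoxide	1.2	1.4	1.1	0.6	0.7	0.5
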