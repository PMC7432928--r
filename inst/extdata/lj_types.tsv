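type	epsilon	rmin_half
CT	0.07	2
CR	0.07	1.99
CO	0.1	2
NH	0.2	1.85
OA	0.12	1.7
OH	0.15	1.77
OC	0.12	1.7
OS	0.15	1.77
SA	0.45	2
PA	0.585	2.15
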