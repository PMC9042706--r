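gene	effect	reads	popfreq	lymphoma_relevant
MYD88	exonic_nonsynonymous	450	0.00005	TRUE
BRAF	exonic_nonsynonymous	15	0.00001	TRUE
EZH2	exonic_nonsynonymous	120	0.001	TRUE
KLHL6	splice_site	88	0.00002	FALSE
TP53	exonic_nonsynonymous	95	0.002	FALSE
NOTCH2	synonymous	300	0.00001	FALSE
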