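# Relative-rate test inputs: counts of unique amino-acid substitutions
# on each lineage, polarized with the Tasmanian devil outgroup
# (literature-derived census).
lineage_a	lineage_b	outgroup	n_a	n_b
Human	Dog	Tasmanian_devil	22	15
Human	Panda	Tasmanian_devil	23	12
Human	Horse	Tasmanian_devil	21	19
Human	Pig	Tasmanian_devil	18	25
Mouse	Dog	Tasmanian_devil	48	10
Mouse	Panda	Tasmanian_devil	52	11
Mouse	Horse	Tasmanian_devil	47	15
Mouse	Pig	Tasmanian_devil	44	21
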