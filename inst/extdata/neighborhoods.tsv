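# Ordered gene neighborhoods around the GCKR locus (literature-derived;
# coordinates are schematic rank positions, not assembly coordinates).
# Species without a GCKR hit carry only the flanking anchors that were
# recoverable from their assemblies.
species	fragment	symbol	strand	start
Human	Chr2	IFT172	+	100
Human	Chr2	FNDC4	+	200
Human	Chr2	GCKR	+	300
Human	Chr2	ZNF512	+	400
Human	Chr2	C2ORF16	+	500
Chicken	Chr22	IFT172	+	100
Chicken	Chr22	FNDC4	+	200
Chicken	Chr22	ZNF512	+	300
Chicken	Chr22	C2ORF16	+	400
Chinese_softshell_turtle	JH210441.1	GCKR	+	100
Chinese_softshell_turtle	JH211948.1	GCKR	+	100
Chinese_softshell_turtle	JH211948.1	ZNF512	+	300
Coelacanth	JH127635.1	FNDC4	+	100
Coelacanth	JH127635.1	LDLRAP1	+	200
Coelacanth	JH127635.1	GCKR	+	300
Coelacanth	JH127635.1	PTK6	+	400
Coelacanth	JH127635.1	BLK	+	500
Zebrafish	Chr17	IFT172	+	100
Zebrafish	Chr17	FNDC4	+	200
Zebrafish	Chr17	GCKR	+	300
Zebrafish	Chr17	PTK6	+	400
Takifugu	scaffold_64	FNDC4	+	100
Takifugu	scaffold_64	GCKR	+	200
Takifugu	scaffold_64	XKR6	-	300
Takifugu	scaffold_64	ZNF512	+	400
Shrew	frag_sa1	FNDC4	+	100
Shrew	frag_sa2	ZNF512	+	100
Platypus	frag_oa1	FNDC4	+	100
Platypus	frag_oa2	ZNF512	+	100
Anole_lizard	frag_ac1	FNDC4	+	100
Anole_lizard	frag_ac2	ZNF512	+	100
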