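# Genomic locations of GCKR-like sequences across vertebrate genome
# assemblies: literature-derived census (coordinates transcribed as
# printed in the source survey; found=FALSE marks species where no
# GCKR-like sequence was detected).  One row per genomic fragment.
species	latin_name	contig	start	end	found
Human	Homo_sapiens	Chr2	27719709	27746554	TRUE
Chimpanzee	Pan_troglodytes	Chr2A	27882887	27909760	TRUE
Gorilla	Gorilla_gorilla	Chr2a	27973322	28000831	TRUE
Orangutan	Pongo_abelii	Chr2a	84605694	84632388	TRUE
Gibbon	Nomascus_leucogenys	GL397331.1	6798770	6825699	TRUE
Baboon	Papio_hamadryas	Contig312330_Contig468503	252057	274688	TRUE
Macaque	Macaca_mulatta	Chr13	27491384	27514309	TRUE
Squirrel_monkey	Saimiri_boliviensis	JH378252.1	3026699	3052421	TRUE
Marmoset	Callithrix_jacchus	Chr14	80920115	80945184	TRUE
Marmoset	Callithrix_jacchus	Chr14	8215977	82166805	TRUE
Marmoset	Callithrix_jacchus	GL285667.1	14860	21407	TRUE
Marmoset	Callithrix_jacchus	GL289329.1	2701	8499	TRUE
Tarsier	Tarsius_syrichta	scaffold_142375	1	6848	TRUE
Bushbaby	Otolemur_garnettii	GL873541.1	18431947	18458466	TRUE
Mouse_lemur	Microcebus_murinus	GeneScaffold_1280	170174	180857	TRUE
Mouse_lemur	Microcebus_murinus	scaffold_9408	44808	49358	TRUE
Mouse	Mus_musculus	Chr5	31599954	31629673	TRUE
Rat	Rattus_norvegicus	Chr6	36176192	36204485	TRUE
Chinese_hamster	Cricetulus_griseus	JH000049	3040662	3062034	TRUE
Kangaroo_rat	Dipodomys_ordii	GeneScaffold_1944	64619	93530	TRUE
Guinea_pig	Cavia_porcellus	scaffold_18	9315790	9341258	TRUE
Squirrel	Ictidomys_tridecemlineatus	JH393303	5080559	5101892	TRUE
Pika	Ochotona_princeps	GeneScaffold_1353	89382	113541	TRUE
Rabbit	Oryctolagus_cuniculus	Chr2	158578950	158598892	TRUE
Cow	Bos_taurus	Chr11	72154947	72176344	TRUE
Sheep	Ovis_aries	Chr3	36829349	36855060	TRUE
Dolphin	Tursiops_truncatus	GeneScaffold_1519	243720	266976	TRUE
Pig	Sus_scrofa	Chr3	118796212	118823097	TRUE
Alpaca	Vicugna_pacos	GeneScaffold_2392	230396	239542	TRUE
Horse	Equus_caballus	Chr15	68799209	68819071	TRUE
Dog	Canis_familiaris	Chr17	21434251	21459913	TRUE
Cat	Felis_catus	ChrA3	120477725	120487528	TRUE
Ferret	Mustela_putorius_furo	GL897010.1	4462918	4658018	TRUE
Panda	Ailuropoda_melanoleuca	GL192369.1	463160	487028	TRUE
Little_brown_bat	Myotis_lucifugus	GL430052	860474	888947	TRUE
Flying_fox_bat	Pteropus_vampyrus	GeneScaffold_1035	519562	527386	TRUE
Tree_shrew	Tupaia_belangeri	GeneScaffold_1539	218507	244816	TRUE
Hedgehog	Erinaceus_europaeus	GeneScaffold_2521	113709	138867	TRUE
Shrew	Sorex_araneus	NA	NA	NA	FALSE
Elephant	Loxodonta_africana	scaffold_20	41160463	41182623	TRUE
Hyrax	Procavia_capensis	GeneScaffold_2165	16762	42556	TRUE
Lesser_hedgehog_tenrec	Echinops_telfairi	GeneScaffold_9143	353017	423957	TRUE
Armadillo	Dasypus_novemcinctus	GeneScaffold_3428	67859	94885	TRUE
Sloth	Choloepus_hoffmanni	GeneScaffold_3794	42395	42809	TRUE
Sloth	Choloepus_hoffmanni	scaffold_170360	376	835	TRUE
Sloth	Choloepus_hoffmanni	scaffold_83977	28	3734	TRUE
Opossum	Monodelphis_domestica	Chr1	508848942	508873322	TRUE
Wallaby	Macropus_eugenii	GeneScaffold_1196	275	7845	TRUE
Tasmanian_devil	Sarcophilus_harrisii	GL856719.1	1420689	1458490	TRUE
Platypus	Ornithorhynchus_anatinus	NA	NA	NA	FALSE
Anole_lizard	Anolis_carolinensis	NA	NA	NA	FALSE
Painted_turtle	Chrysemys_picta_bellii	JH585650.1	8656	43647	TRUE
Chinese_softshell_turtle	Pelodiscus_sinensis	JH210441.1	6448	7388	TRUE
Chinese_softshell_turtle	Pelodiscus_sinensis	JH211948.1	132429	114901	TRUE
Chicken	Gallus_gallus	NA	NA	NA	FALSE
Turkey	Meleagris_gallopavo	NA	NA	NA	FALSE
Zebra_finch	Taeniopygia_guttata	NA	NA	NA	FALSE
Budgerigar	Melopsittacus_undulatus	NA	NA	NA	FALSE
Duck	Anas_platyrhynchos	NA	NA	NA	FALSE
Western_clawed_frog	Xenopus_tropicalis	GL176436.1	2467	2564	TRUE
Western_clawed_frog	Xenopus_tropicalis	GL175638.1	1885	7075	TRUE
Western_clawed_frog	Xenopus_tropicalis	GL181463.1	68	7426	TRUE
Western_clawed_frog	Xenopus_tropicalis	GL175969.1	6442	11214	TRUE
African_clawed_frog	Xenopus_laevis	NA	NA	NA	TRUE
Coelacanth	Latimeria_chalumnae	JH127635.1	202083	223756	TRUE
Cod	Gadus_morhua	NA	NA	NA	FALSE
Takifugu	Takifugu_rubripes	scaffold_64	713339	722055	TRUE
Medaka	Oryzias_latipes	Chr2	24524153	24535721	TRUE
Stickleback	Gasterosteus_aculeatus	groupI	23443090	23447491	TRUE
Tetraodon	Tetraodon_nigroviridis	Chr3	4336678	4340938	TRUE
Zebrafish	Danio_rerio	Chr17	5624859	5639741	TRUE
Tilapia	Oreochromis_niloticus	GL831144.1	2399129	2414317	TRUE
Platyfish	Xiphophorus_maculatus	JH556962.1	106171	111589	TRUE
Spotted_gar	Lepisosteus_oculatus	LG1	45522798	45550720	TRUE
Lamprey	Petromyzon_marinus	GL476557	253805	279336	TRUE
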