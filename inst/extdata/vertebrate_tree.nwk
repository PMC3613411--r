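(Lamprey,((Spotted_gar,(Zebrafish,(Cod,((Takifugu,Tetraodon),(Medaka,(Stickleback,(Tilapia,Platyfish))))))),(Coelacanth,((Western_clawed_frog,African_clawed_frog),((Anole_lizard,((Painted_turtle,Chinese_softshell_turtle),(((Chicken,Turkey),Duck),(Zebra_finch,Budgerigar)))),(Platypus,((Opossum,(Wallaby,Tasmanian_devil)),(((Armadillo,Sloth),((Elephant,Hyrax),Lesser_hedgehog_tenrec)),((((((((((Human,Chimpanzee),Gorilla),Orangutan),Gibbon),(Baboon,Macaque)),(Squirrel_monkey,Marmoset)),Tarsier),(Bushbaby,Mouse_lemur)),Tree_shrew),((Squirrel,(Guinea_pig,(Kangaroo_rat,((Mouse,Rat),Chinese_hamster)))),(Rabbit,Pika))),((Hedgehog,Shrew),((Alpaca,(Pig,((Cow,Sheep),Dolphin))),(Horse,((Cat,(Dog,(Ferret,Panda))),(Little_brown_bat,Flying_fox_bat)))))))))))));
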