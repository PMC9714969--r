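species,genus,clade,n,n_left,n_right,n_ambi,pct_left,pct_right,pct_ambi,mean_hi,mean_abs_hi
Ateles fusciceps,Ateles,Platyrrhini,46,20,22,4,43.5,47.8,8.7,0.063,0.798
Ateles geoffroyi,Ateles,Platyrrhini,23,10,11,2,43.5,47.8,8.7,0.061,0.829
Ateles hybridus,Ateles,Platyrrhini,18,13,5,0,72.2,27.8,0,-0.377,0.917
Cercocebus torquatus,Cercocebus,Cercopithecoidea,31,13,11,7,41.9,35.5,22.6,-0.029,0.665
Cercopithecus diana,Cercopithecus,Cercopithecoidea,20,7,10,3,35,50,15,0.178,0.755
Cercopithecus neglectus,Cercopithecus,Cercopithecoidea,25,14,7,4,56,28,16,-0.258,0.621
Gorilla gorilla,Gorilla,Hominoidea,76,17,41,18,22.4,53.9,23.7,0.248,0.541
Homo sapiens,Homo,Hominoidea,127,12,111,4,9.5,87.4,3.1,0.761,0.943
Hylobates lar,Hylobates,Hominoidea,36,17,16,3,47.2,44.5,8.3,-0.011,0.614
Hylobates moloch,Hylobates,Hominoidea,22,11,8,3,50,36.4,13.6,-0.115,0.799
Leontopithecus chrysomelas,Leontopithecus,Platyrrhini,30,7,12,11,23.3,40,36.7,0.151,0.514
Leontopithecus chrysopygus,Leontopithecus,Platyrrhini,15,3,4,8,20,26.7,53.3,0.039,0.350
Leontopithecus rosalia,Leontopithecus,Platyrrhini,28,10,8,10,35.7,28.6,35.7,0.022,0.502
Macaca fascicularis,Macaca,Cercopithecoidea,20,8,10,2,45,45,10,-0.036,0.684
Macaca nemestrina,Macaca,Cercopithecoidea,29,9,11,9,31,37.9,31,0.035,0.527
Macaca silenus,Macaca,Cercopithecoidea,35,14,9,12,40,25.7,34.3,-0.051,0.467
Macaca sylvanus,Macaca,Cercopithecoidea,24,12,10,2,50,41.7,8.3,-0.025,0.670
Macaca tonkeana,Macaca,Cercopithecoidea,14,5,3,6,35.7,21.4,42.9,-0.057,0.543
Mandrillus sphinx,Mandrillus,Cercopithecoidea,32,6,10,16,18.8,31.2,50,0.034,0.389
Nomascus gabriellae,Nomascus,Hominoidea,10,5,2,3,50,20,30,-0.173,0.618
Nomascus leucogenys,Nomascus,Hominoidea,26,9,11,6,34.6,42.3,23.1,-0.031,0.555
Pan paniscus,Pan,Hominoidea,118,50,51,17,42.4,43.2,14.4,0.044,0.529
Pan troglodytes,Pan,Hominoidea,536,155,266,115,28.9,49.6,21.5,0.133,0.507
Papio anubis,Papio,Cercopithecoidea,84,27,41,16,32.1,48.8,19.1,0.108,0.527
Papio hamadryas,Papio,Cercopithecoidea,24,6,7,11,25,29.2,45.8,0.066,0.408
Pithecia pithecia,Pithecia,Platyrrhini,7,5,2,0,71.4,28.6,0,-0.385,0.934
Pongo sp.,Pongo,Hominoidea,47,27,9,11,57.5,19.1,23.4,-0.225,0.487
Pygathrix cinerea,Pygathrix,Cercopithecoidea,18,6,10,2,33.3,55.6,11.1,0.165,0.499
Rhinopithecus roxellana,Rhinopithecus,Cercopithecoidea,24,17,7,0,70.8,29.2,0,-0.319,0.729
Saimiri sciureus,Saimiri,Platyrrhini,36,21,14,1,58.4,38.9,2.7,-0.119,0.757
Sapajus apella,Sapajus,Platyrrhini,25,11,10,4,44,40,16,-0.028,0.687
Sapajus flavius,Sapajus,Platyrrhini,21,10,7,4,47.6,33.3,19,-0.130,0.769
Sapajus xanthosternos,Sapajus,Platyrrhini,34,14,15,5,41.2,44.1,14.7,0.089,0.677
Semnopithecus entellus,Semnopithecus,Cercopithecoidea,30,15,7,8,50,23.4,26.6,-0.184,0.560
Symphalangus syndactylus,Symphalangus,Hominoidea,31,11,9,11,35.5,29,35.5,-0.048,0.482
Theropithecus gelada,Theropithecus,Cercopithecoidea,38,6,6,26,15.8,15.8,68.4,0.053,0.257
Trachypithecus auratus,Trachypithecus,Cercopithecoidea,8,5,3,0,62.5,37.5,0,-0.256,0.984
Trachypithecus hatinhensis,Trachypithecus,Cercopithecoidea,18,11,7,0,61.1,38.9,0,-0.248,0.817
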