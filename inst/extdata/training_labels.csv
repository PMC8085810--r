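species,label,role
Alliphis halleri,worm_like,test
Alliphis siculus,worm_like,training
Amblyseius okanagensis,unknown,test
Ameroseius sp.,unknown,test
Androlaelaps casalis,unknown,test
Arctoseius brevicheles,unknown,test
Arctoseius certratus,polyphagous,training
Arctoseius minutus,unknown,test
Arctoseius venustulus,unknown,test
Blattisocius keegani,polyphagous,training
Cheiroseius borealis,polyphagous,training
Dendrolaelaps foveolatus,known_but_unprinted,training
Eugamasus berlesei,unknown,test
Eugamasus cavernicola,unknown,test
Eviphis ostrinus,known_but_unprinted,training
Geholaspis longispinosus,known_but_unprinted,training
Geholaspis sp.,known_but_unprinted,training
Glyphtholaspis confusa,worm_like,test
Hypoaspis aculeifer,polyphagous,training
Hypoaspis angustiscutata,known_but_unprinted,training
Iphidozercon gibbus,unknown,test
Leioseius bicolor,unknown,test
Macrocheles montanus,known_but_unprinted,training
Pachylaelaps furcifer,unknown,test
Pachylaelaps leauchlii,unknown,test
Pachyseius humeralis,known_but_unprinted,training
Parasitus beta,unknown,test
Parasitus coleoptratorum DN,worm_like,test
Parasitus fucorum DN,ambiguous,test
Parasitus lunaris DN,unknown,test
Parazercon radiatus,known_but_unprinted,training
Pergamasus cornutus,unknown,test
Pergamasus crassipes,polyphagous,training
Pergamasus digitulus,known_but_unprinted,training
Pergamasus mirabilis,unknown,test
Pergamasus misellus,known_but_unprinted,training
Pergamasus oxygynelloides,unknown,test
Pergamasus quisquillarum,known_but_unprinted,training
Pergamasus runcatellus,polyphagous,training
Pergamasus runciger,polyphagous,training
Pergamasus septentrionalis,polyphagous,training
Pergamasus sp,unknown,test
Pergamasus suecicus,known_but_unprinted,training
Polyaspis n.sp. DN,worm_like,test
Porrhostaspis lunulata,unknown,test
Proctolaelaps pygmaeus,omnivore,training
Rhodacarellus epigynalis,unknown,test
Rhodacarellus sileciacus,polyphagous,training
Rhodacarus agrestis,unknown,test
Rhodacarus strenzkei,unknown,test
Trachytes aegrota,omnivore,training
Typhlodromus setubali,unknown,test
Urodiaspis tecta,unknown,test
Uropoda orbicularis DN,worm_like,test
Veigaia cerva,microarthropod,training
Veigaia decurtata,unknown,test
Veigaia exigua,microarthropod,training
Veigaia nemorensis (new),microarthropod,test
Veigaia nemorensis (old),microarthropod,training
Zercon peliatus,unknown,test
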