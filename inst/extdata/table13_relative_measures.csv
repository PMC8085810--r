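species,CL_IL,MDL_IL,MDL_CL,F2AV_IL
Alliphis halleri,30.6,8.0,26.3,0.88
Alliphis siculus,29.9,7.9,26.4,6.89
Amblyseius okanagensis,32.4,8.4,26.0,1.19
Ameroseius sp.,24.5,5.7,23.0,0.76
Androlaelaps casalis,28.5,6.0,21.2,0.99
Arctoseius brevicheles,36.4,6.2,17.0,1.45
Arctoseius certratus,37.5,9.5,25.3,1.26
Arctoseius minutus,33.0,7.2,21.9,0.89
Arctoseius venustulus,35.4,8.2,23.1,0.89
Blattisocius keegani,24.5,5.6,22.8,1.19
Cheiroseius borealis,43.1,10.0,23.2,0.97
Dendrolaelaps foveolatus,32.0,8.3,25.9,1.43
Eugamasus berlesei,32.7,9.8,30.1,2.99
Eugamasus cavernicola,35.7,10.4,29.1,2.66
Eviphis ostrinus,61.2,7.5,12.2,0.92
Geholaspis longispinosus,37.8,9.3,24.5,1.91
Geholaspis sp.,48.2,24.2,50.3,3.17
Glyphtholaspis confusa,38.1,9.5,24.9,4.09
Hypoaspis aculeifer,43.4,13.2,30.5,1.95
Hypoaspis angustiscutata,43.6,13.4,30.8,2.09
Iphidozercon gibbus,44.6,6.7,15.1,1.07
Leioseius bicolor,36.0,9.4,26.1,1.08
Macrocheles montanus,35.8,10.1,28.1,3.21
Pachylaelaps furcifer,34.9,9.7,27.7,1.17
Pachylaelaps leauchlii,36.5,10.3,28.1,1.32
Pachyseius humeralis,31.3,9.0,28.6,0.84
Parasitus beta,29.1,8.1,27.9,1.26
Parasitus coleoptratorum DN,40.0,11.5,28.8,3.72
Parasitus fucorum DN,33.4,9.0,26.9,2.93
Parasitus lunaris DN,57.3,19.2,33.5,2.08
Parazercon radiatus,40.5,9.1,22.5,1.77
Pergamasus cornutus,39.6,14.5,36.7,1.88
Pergamasus crassipes,37.6,14.7,39.0,3.01
Pergamasus digitulus,39.5,14.3,36.2,1.56
Pergamasus mirabilis,54.2,20.6,38.0,3.43
Pergamasus misellus,36.9,13.5,36.6,1.43
Pergamasus oxygynelloides,41.8,17.3,41.3,1.78
Pergamasus quisquillarum,44.7,16.3,36.5,4.18
Pergamasus runcatellus,41.3,16.2,39.2,2.74
Pergamasus runciger,40.1,15.3,38.2,2.57
Pergamasus septentrionalis,45.0,16.0,35.5,5.6
Pergamasus sp,41.6,16.1,38.7,2.38
Pergamasus suecicus,45.8,17.0,37.1,1.67
Polyaspis n.sp. DN,43.3,15.4,35.6,1.11
Porrhostaspis lunulata,38.8,11.9,30.6,1.52
Proctolaelaps pygmaeus,31.9,7.1,22.1,1.41
Rhodacarellus epigynalis,42.2,14.2,33.7,3.11
Rhodacarellus sileciacus,37.6,11.0,29.3,1.44
Rhodacarus agrestis,53.2,21.2,39.8,3.17
Rhodacarus strenzkei,55.9,22.8,40.8,5.76
Trachytes aegrota,45.5,4.4,9.7,0.51
Typhlodromus setubali,34.4,7.8,22.8,1.3
Urodiaspis tecta,39.8,3.0,7.6,0.47
Uropoda orbicularis DN,39.9,3.4,8.6,1.09
Veigaia cerva,98.3,37.4,38.1,3.65
Veigaia decurtata,75.6,27.9,36.9,1.19
Veigaia exigua,75.1,29.1,38.7,1.52
Veigaia nemorensis (new),70.1,22.5,32.1,2.69
Veigaia nemorensis (old),63.5,23.0,36.1,3.17
Zercon peliatus,34.5,9.0,26.1,1.13
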