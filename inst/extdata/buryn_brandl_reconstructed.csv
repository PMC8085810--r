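species,Id,m1,m7,m2
Alliphis siculus,482.0,97.0,38.0,64.0
Amblyseius okanagensis,396.0,86.0,33.3,29.0
Ameroseius sp.,381.0,61.5,21.5,21.3
Androlaelaps casalis,657.0,121.8,39.6,32.3
Arctoseius brevicheles,405.0,93.0,25.0,27.0
Arctoseius certratus,344.7,86.4,32.7,27.8
Arctoseius minutus,342.3,73.7,24.7,22.0
Arctoseius venustulus,407.7,95.0,33.3,25.3
Blattisocius keegani,478.0,77.0,26.7,29.0
Cheiroseius borealis,567.5,161.0,56.7,32.8
Dendrolaelaps foveolatus,388.3,83.3,32.1,30.7
Eugamasus berlesei,1292.0,291.0,127.0,91.0
Eugamasus cavernicola,1164.7,285.0,121.0,81.8
Eviphis ostrinus,536.0,200.0,40.0,24.0
Geholaspis longispinosus,988.1,248.1,91.3,60.5
Geholaspis sp.,822.8,308.5,199.0,96.7
Hypoaspis aculeifer,757.0,227.0,100.0,59.0
Hypoaspis angustiscutata,799.0,241.0,107.0,62.9
Iphidozercon gibbus,427.0,118.5,28.6,24.0
Leioseius bicolor,361.5,87.5,34.0,27.0
Macrocheles montanus,1255.0,305.8,126.0,90.9
Pachylaelaps furcifer,942.0,223.0,91.0,50.0
Pachylaelaps leauchlii,860.3,213.7,88.2,50.6
Pachyseius humeralis,627.6,134.2,56.2,34.3
Parasitus beta,643.0,127.0,52.0,40.0
Parazercon radiatus,350.0,93.0,31.9,31.0
Pergamasus cornutus,616.9,175.4,89.5,55.0
Pergamasus crassipes,1147.0,313.8,167.8,97.9
Pergamasus digitulus,497.2,140.4,70.8,44.5
Pergamasus mirabilis,771.0,302.5,158.5,86.3
Pergamasus misellus,532.3,141.0,71.8,44.5
Pergamasus oxygynelloides,557.0,172.0,96.0,54.0
Pergamasus quisquillarum,1227.6,393.5,199.8,117.0
Pergamasus runcatellus,694.3,208.9,112.1,71.2
Pergamasus runciger,792.9,230.4,121.3,74.0
Pergamasus septentrionalis,1323.3,424.0,210.7,136.2
Pergamasus sp,643.2,194.4,103.2,64.2
Pergamasus suecicus,447.9,147.7,75.9,44.8
Porrhostaspis lunulata,1036.0,278.0,123.0,63.1
Proctolaelaps pygmaeus,374.9,78.1,26.4,27.9
Rhodacarellus epigynalis,420.1,124.9,59.6,51.9
Rhodacarellus sileciacus,299.3,77.2,32.9,28.7
Rhodacarus agrestis,445.3,173.5,94.2,61.3
Rhodacarus strenzkei,586.3,241.4,133.4,93.5
Trachytes aegrota,679.6,185.1,29.9,18.3
Typhlodromus setubali,314.0,71.0,24.6,25.0
Urodiaspis tecta,728.0,171.0,22.0,16.0
Veigaia cerva,817.2,581.5,305.0,102.0
Veigaia decurtata,378.8,206.0,105.5,38.4
Veigaia exigua,395.7,216.0,114.8,44.9
Veigaia nemorensis (old),671.4,305.3,153.9,77.6
Zercon peliatus,456.2,105.8,41.1,31.3
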