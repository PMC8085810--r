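species,IL,CL,MDL,VR,F2AV,AR
Alliphis halleri,469.6,143.5,37.7,0.357,415.3,5.4
Alliphis siculus,481.1,143.9,38.0,0.745,3314.1,2.17
Amblyseius okanagensis,395.2,127.9,33.3,0.385,470.6,4.26
Ameroseius sp.,380.3,93.3,21.5,0.438,290.5,4.23
Androlaelaps casalis,655.8,187.2,39.6,0.361,646.0,5.59
Arctoseius brevicheles,404.2,147.1,25.0,0.478,584.8,5.26
Arctoseius certratus,344.0,129.1,32.7,0.376,434.6,4.48
Arctoseius minutus,341.6,112.7,24.7,0.394,304.1,4.94
Arctoseius venustulus,406.9,144.1,33.3,0.336,362.9,5.5
Blattisocius keegani,477.1,117.0,26.7,0.48,566.7,3.89
Cheiroseius borealis,566.4,244.0,56.7,0.256,546.7,7.18
Dendrolaelaps foveolatus,387.6,124.0,32.1,0.423,554.4,3.9
Eugamasus berlesei,1289.5,421.5,127.0,0.317,3857.8,4.47
Eugamasus cavernicola,1162.5,415.5,121.0,0.299,3090.0,4.91
Eviphis ostrinus,535.0,327.3,40.0,0.265,490.6,13.16
Geholaspis longispinosus,986.2,372.9,91.3,0.293,1886.7,5.95
Geholaspis sp.,821.2,395.6,199.0,0.215,2601.6,3.95
Glyphtholaspis confusa,1434.7,546.6,136.0,0.406,5867.8,5.74
Hypoaspis aculeifer,755.6,328.0,100.0,0.261,1472.4,5.37
Hypoaspis angustiscutata,797.5,347.6,107.0,0.26,1666.4,5.32
Iphidozercon gibbus,426.2,190.0,28.6,0.371,456.7,7.64
Leioseius bicolor,360.8,130.1,34.0,0.351,389.4,4.65
Macrocheles montanus,1252.6,448.8,126.0,0.319,4025.8,4.77
Pachylaelaps furcifer,940.2,328.0,91.0,0.243,1096.1,6.33
Pachylaelaps leauchlii,858.7,313.5,88.2,0.254,1136.3,5.97
Pachyseius humeralis,626.4,196.3,56.2,0.27,526.7,5.52
Parasitus beta,641.8,186.7,52.0,0.34,809.4,4.5
Parasitus coleoptratorum DN,1280.5,511.6,147.3,0.276,4762.3,4.46
Parasitus fucorum DN,1074.3,358.5,96.6,0.334,3145.2,4.16
Parasitus lunaris DN,628.1,359.8,120.6,0.202,1305.3,5.5
Parazercon radiatus,349.3,141.6,31.9,0.43,617.9,4.41
Pergamasus cornutus,615.7,243.7,89.5,0.272,1156.4,4.28
Pergamasus crassipes,1144.8,430.0,167.8,0.258,3445.5,4.23
Pergamasus digitulus,496.3,195.8,70.8,0.278,772.9,4.25
Pergamasus mirabilis,769.5,417.1,158.5,0.241,2639.6,4.65
Pergamasus misellus,531.3,196.1,71.8,0.274,761.5,4.25
Pergamasus oxygynelloides,555.9,232.5,96.0,0.249,990.9,4.15
Pergamasus quisquillarum,1225.3,547.6,199.8,0.259,5118.9,4.52
Pergamasus runcatellus,693.0,285.9,112.1,0.281,1901.2,3.87
Pergamasus runciger,791.4,317.2,121.3,0.27,2034.1,4.14
Pergamasus septentrionalis,1320.8,593.7,210.7,0.286,7401.0,4.21
Pergamasus sp,642.0,267.0,103.2,0.275,1530.4,4.02
Pergamasus suecicus,447.0,204.8,75.9,0.261,747.7,4.41
Polyaspis n.sp. DN,846.4,366.6,130.4,0.199,938.0,7.31
Porrhostaspis lunulata,1034.0,401.3,123.0,0.227,1576.2,6.15
Proctolaelaps pygmaeus,374.2,119.2,26.4,0.468,526.4,4.12
Rhodacarellus epigynalis,419.3,176.9,59.6,0.385,1302.6,3.29
Rhodacarellus sileciacus,298.7,112.4,32.9,0.386,430.9,3.78
Rhodacarus agrestis,444.5,236.6,94.2,0.288,1409.9,3.72
Rhodacarus strenzkei,585.2,327.3,133.4,0.31,3373.3,3.38
Trachytes aegrota,678.3,308.6,29.9,0.271,348.7,16.27
Typhlodromus setubali,313.4,107.9,24.6,0.45,407.7,4.17
Urodiaspis tecta,726.6,289.5,22.0,0.322,338.9,17.46
Uropoda orbicularis DN,682.0,272.3,23.4,0.458,741.6,12.93
Veigaia cerva,815.6,801.5,305.0,0.148,2979.9,7.58
Veigaia decurtata,378.1,286.0,105.5,0.161,449.3,7.17
Veigaia exigua,394.9,296.5,114.8,0.173,602.0,6.39
Veigaia nemorensis (new),678.4,475.4,152.4,0.22,1824.2,6.95
Veigaia nemorensis (old),670.1,425.8,153.9,0.223,2123.5,5.29
Zercon peliatus,455.3,157.3,41.1,0.337,513.4,4.85
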