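species,VR,predicted,p_hat,agreement,flag_inconsistent
Alliphis halleri,0.357,worm_like,0.569,✓,0
Amblyseius okanagensis,0.385,worm_like,0.597,,0
Ameroseius sp.,0.438,worm_like,0.644,,0
Androlaelaps casalis,0.361,worm_like,0.574,,0
Arctoseius brevicheles,0.478,worm_like,0.675,,0
Arctoseius minutus,0.394,worm_like,0.606,,0
Arctoseius venustulus,0.336,worm_like,0.547,,0
Eugamasus berlesei,0.317,worm_like,0.526,,0
Eugamasus cavernicola,0.299,worm_like,0.504,,0
Glyphtholaspis confusa,0.406,worm_like,0.616,✓,0
Iphidozercon gibbus,0.371,worm_like,0.584,,0
Leioseius bicolor,0.351,worm_like,0.564,,0
Pachylaelaps furcifer,0.243,microarthropod,0.431,,0
Pachylaelaps leauchlii,0.254,microarthropod,0.447,,0
Parasitus beta,0.34,worm_like,0.552,,0
Parasitus coleoptratorum DN,0.276,worm_like,0.476,✓,0
Parasitus fucorum DN,0.334,worm_like,0.545,✛,0
Parasitus lunaris DN,0.202,microarthropod,0.369,,0
Pergamasus cornutus,0.272,microarthropod,0.471,,0
Pergamasus mirabilis,0.241,microarthropod,0.429,,0
Pergamasus oxygynelloides,0.249,microarthropod,0.439,,0
Pergamasus sp,0.275,microarthropod,0.474,,0
Polyaspis n.sp. DN,0.199,microarthropod,0.365,✗,0
Porrhostaspis lunulata,0.227,microarthropod,0.407,,0
Rhodacarellus epigynalis,0.385,worm_like,0.597,,0
Rhodacarus agrestis,0.288,worm_like,0.491,,0
Rhodacarus strenzkei,0.31,worm_like,0.518,,0
Typhlodromus setubali,0.45,worm_like,0.645,,1
Urodiaspis tecta,0.322,worm_like,0.532,,0
Uropoda orbicularis DN,0.458,worm_like,0.66,✓,0
Veigaia decurtata,0.161,microarthropod,0.301,,0
Veigaia nemorensis (new),0.22,microarthropod,0.397,✓,0
Zercon peliatus,0.337,worm_like,0.548,,0
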