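species,stage,MD_ratio,VR,vr_source,VR_main_study,proposed_feeding
Cornigamasus lunaris,DN,0.349,0.242,predicted,0.202,microarthropod
Cornigamasus lunaris,male,0.314,0.218,predicted,,microarthropod
Cornigamasus lunaris,female,0.413,0.203,measured,,microarthropod
Eugamasus berlesei,DN,0.318,0.216,measured,,microarthropod
Eugamasus berlesei,male,0.322,0.223,predicted,,microarthropod
Eugamasus berlesei,female,0.349,0.214,measured,0.317,microarthropod
Eugamasus cavernicola,female,0.44,0.264,measured,0.299,microarthropod
Eugamasus crassitarsis,male,0.356,0.185,measured,,microarthropod
Eugamasus crassitarsis,female,0.394,0.368,measured,,worm_like
Eugamasus magnus,male,0.398,0.276,predicted,,worm_like
Gamasodes bispinosus,DN,0.413,0.287,predicted,,worm_like
Gamasodes bispinosus,male,0.377,0.261,predicted,,microarthropod
Gamasodes bispinosus,female,0.364,0.252,predicted,,microarthropod
Gamasodes fimbriatus,male,0.319,0.221,predicted,,microarthropod
Gamasodes fimbriatus,female,0.395,0.289,measured,,worm_like
Gamasodes spiniger,DN,0.482,0.335,predicted,,worm_like
Gamasodes spiniger,male,0.318,0.221,predicted,,microarthropod
Gamasodes spiniger,female,0.392,0.215,measured,,microarthropod
Parasitellus crinitus,DN,0.403,0.233,measured,,microarthropod
Parasitellus crinitus,male,0.425,0.295,predicted,,worm_like
Parasitellus crinitus,female,0.359,0.225,measured,,microarthropod
Parasitellus fucorum,DN,0.459,0.318,predicted,0.334,worm_like
Parasitellus fucorum,male,0.299,0.207,predicted,,microarthropod
Parasitellus fucorum,female,0.277,0.23,measured,,microarthropod
Parasitellus ignotus,DN,0.436,0.271,measured,,microarthropod
Parasitellus ignotus,male,0.371,0.351,measured,,worm_like
Parasitellus ignotus,female,0.356,0.336,measured,,worm_like
Parasitellus talparum,DN,0.456,0.283,measured,,worm_like
Parasitellus talparum,male,0.333,0.381,measured,,worm_like
Parasitellus talparum,female,0.344,0.297,measured,,worm_like
Parasitus beta,DN,0.407,0.282,predicted,,worm_like
Parasitus beta,male,0.154,0.107,predicted,,microarthropod
Parasitus beta,female,0.392,0.295,measured,0.34,worm_like
Parasitus coleoptratorum,DN,0.393,0.265,measured,0.276,microarthropod
Parasitus coleoptratorum,male,0.367,0.255,predicted,,microarthropod
Parasitus coleoptratorum,female,0.351,0.259,measured,,microarthropod
Parasitus consanguineous,DN,0.388,0.312,measured,,worm_like
Parasitus consanguineous,male,0.293,0.203,predicted,,microarthropod
Parasitus consanguineous,female,0.366,0.283,measured,,worm_like
Parasitus copridis,DN,0.336,0.306,measured,,worm_like
Parasitus copridis,male,0.365,0.253,predicted,,microarthropod
Parasitus copridis,female,0.307,0.258,measured,,microarthropod
Parasitus evertsi,male,0.33,0.229,predicted,,microarthropod
Parasitus evertsi,female,0.308,0.287,measured,,worm_like
Parasitus fimetorum,Larva,0.466,0.323,predicted,,worm_like
Parasitus fimetorum,PN,0.476,0.33,predicted,,worm_like
Parasitus fimetorum,DN,0.369,0.256,predicted,,microarthropod
Parasitus fimetorum,male,0.163,0.113,predicted,,microarthropod
Parasitus fimetorum,female,0.348,0.241,predicted,,microarthropod
Parasitus hyalinus,female,0.403,0.28,predicted,,worm_like
Parasitus insignis,DN,0.326,0.26,measured,,microarthropod
Parasitus insignis,male,0.296,0.205,predicted,,microarthropod
Parasitus insignis,female,0.33,0.237,measured,,microarthropod
Parasitus kempersi,DN,0.357,0.279,measured,,worm_like
Parasitus kempersi,male,0.343,0.238,predicted,,microarthropod
Parasitus kempersi,female,0.336,0.216,measured,,microarthropod
Parasitus loricatus,DN,0.381,0.264,predicted,,microarthropod
Parasitus loricatus,male,0.435,0.301,predicted,,worm_like
Parasitus loricatus,female,0.295,0.17,measured,,microarthropod
Parasitus mustelarum,DN,0.401,0.267,measured,,microarthropod
Parasitus mustelarum,male,0.312,0.217,predicted,,microarthropod
Parasitus mustelarum,female,0.54,0.281,measured,,worm_like
Poecilochirus austroasiaticus,DN,0.467,0.324,predicted,,worm_like
Poecilochirus austroasiaticus,male,0.421,0.292,predicted,,worm_like
Poecilochirus austroasiaticus,female,0.424,0.294,predicted,,worm_like
Poecilochirus carabi,PN,0.349,0.242,predicted,,microarthropod
Poecilochirus carabi,DN,0.355,0.246,predicted,,microarthropod
Poecilochirus carabi,male,0.377,0.262,predicted,,microarthropod
Poecilochirus carabi,female,0.345,0.215,measured,,microarthropod
Poecilochirus davydovae,DN,0.453,0.315,predicted,,worm_like
Poecilochirus davydovae,male,0.329,0.229,predicted,,microarthropod
Poecilochirus davydovae,female,0.406,0.281,predicted,,worm_like
Poecilochirus subterraneus,DN,0.406,0.264,measured,,microarthropod
Porrhostaspis lunulata,DN,0.335,0.342,measured,,worm_like
Porrhostaspis lunulata,male,0.27,0.187,predicted,,microarthropod
Porrhostaspis lunulata,female,0.303,0.21,predicted,0.227,microarthropod
Trachygamasus ambulacralis,DN,0.52,0.361,predicted,,worm_like
Trachygamasus ambulacralis,male,0.419,0.29,predicted,,worm_like
Trachygamasus ambulacralis,female,0.391,0.272,predicted,,microarthropod
Vulgarogamasus burchanensis,male,0.276,0.191,predicted,,microarthropod
Vulgarogamasus burchanensis,female,0.353,0.213,measured,,microarthropod
Vulgarogamasus immanis,DN,0.295,0.17,measured,,microarthropod
Vulgarogamasus immanis,male,0.244,0.169,predicted,,microarthropod
Vulgarogamasus immanis,female,0.284,0.197,predicted,,microarthropod
Vulgarogamasus kraepelini,DN,0.348,0.217,measured,,microarthropod
Vulgarogamasus kraepelini,male,0.401,0.207,measured,,microarthropod
Vulgarogamasus kraepelini,female,0.341,0.26,measured,,microarthropod
Vulgarogamasus oudemansi,DN,0.39,0.263,measured,,microarthropod
Vulgarogamasus oudemansi,male,0.389,0.386,measured,,worm_like
Vulgarogamasus oudemansi,female,0.355,0.196,measured,,microarthropod
Vulgarogamasus remberti,DN,0.412,0.189,measured,,microarthropod
Vulgarogamasus remberti,male,0.435,0.302,predicted,,worm_like
Vulgarogamasus remberti,female,0.342,0.192,measured,,microarthropod
Vulgarogamasus trouessarti,DN,0.372,0.206,measured,,microarthropod
Vulgarogamasus trouessarti,male,0.305,0.212,predicted,,microarthropod
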