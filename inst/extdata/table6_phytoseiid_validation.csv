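source,group,species,DPFD_VPMD,VR,p_worm,F2AV,AR
Adar,Generalist,Amblyseius largoensis,0.903,0.472,0.672,,
Adar,Generalist,Amblyseius swirskii,0.928,0.485,0.684,,
Adar,Generalist,Kampimodromus aberrans,1.139,0.387,0.593,,
Adar,Generalist,Neoseiulus cucumeris,0.899,0.442,0.646,,
Adar,Generalist,Phytoseius plumifer,1.077,0.376,0.582,,
Adar,Generalist,Typhlodromus exhilaratus,1.052,0.375,0.581,,
Adar,Generalist,Typhlodromus pyri,1.029,0.408,0.614,,
Liu,Generalist,<various>,0.925,0.46,0.662,556.9,4.02
Adar,Pollen,Euseius ovalis,1.164,0.362,0.568,,
Adar,Pollen,Euseius scutalis,1.17,0.349,0.555,,
Liu,Pollen,Euseius utilis,1.108,0.443,0.646,454.3,3.17
Adar,Pollen,Iphiseius degenerans,1.069,0.418,0.623,,
Adar,Specialist,Neoseiulus californicus,0.885,0.55,0.735,,
Adar,Specialist,Phytoseiulus longipes,0.963,0.397,0.604,,
Adar,Specialist,Phytoseiulus persimilis,0.932,0.436,0.64,,
Liu,Specialist,<various>,0.915,0.454,0.657,347.4,4.06
BurynBrandl,?,Amblyseius okanagensis,,0.385,0.597,470.6,4.26
BurynBrandl,?,Typhlodromus setualbi,,0.45,0.645,407.7,4.17
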