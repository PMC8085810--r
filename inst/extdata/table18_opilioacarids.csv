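species,stage_sex,DSL,BSL,CL,MDL,F2AV,L1,L2,VR,HDS,HBS
Brasilacarus cocaris,female,269.7,70.8,340.4,89.0,17345.4,44.2,87.9,0.503,147.3,201.8
Brasilacarus cocaris,male,229.3,61.0,290.4,77.1,7348.7,34.3,74.7,0.459,96.5,130.8
Brasilacarus cocaris,female,,,,76.2,,,,,,
Caribeacarus armasi,male,198.8,85.2,284.0,77.3,10957.5,39.7,73.6,0.539,114.7,149.8
Caribeacarus armasi,male,204.4,91.8,296.2,80.7,11388.1,41.3,75.5,0.546,115.6,150.8
Caribeacarus brasiliensis,male,227.6,201.2,428.7,90.1,11728.5,34.9,88.8,0.393,137.6,161.0
Neocarus bajacalifornicus chamelaensis,male,167.7,128.8,296.5,59.6,7854.2,27.7,60.9,0.455,104.9,127.2
Neocarus belizensis,female,,,,,,,,0.506,,
Neocarus belizensis,male,,,,,,,,0.528,,
Neocarus caipora,female,381.2,256.7,637.9,125.6,34429.1,58.8,126.8,0.464,220.2,255.9
Neocarus calakmulensis,female,148.5,115.6,264.1,56.8,4088.5,20.7,54.7,0.379,81.3,97.4
Neocarus chactemalensis,female,239.8,169.3,409.1,93.3,13456.3,36.9,86.5,0.427,141.7,173.2
Neocarus comalensis,female,,,,73.5,,27.7,74.7,0.371,,
Neocarus proteus,larva,151.9,86.8,238.7,50.6,4259.0,21.0,50.4,0.417,80.9,96.3
Neocarus proteus,dn,171.6,112.6,284.2,57.6,5611.8,24.5,56.5,0.434,92.9,102.8
Neocarus proteus,tn,190.5,105.8,296.3,59.9,5046.3,20.4,59.1,0.346,96.5,112.5
Neocarus proteus,female,201.7,131.2,332.9,72.5,7287.2,30.7,70.8,0.433,100.7,122.3
Neocarus texanus,female,,,,89.2,,39.0,93.2,0.418,,
Neocarus veracruzensis,female,,,,86.5,,38.9,83.0,0.468,,
Neocarus veracruzensis,male,233.4,133.2,366.6,85.7,11060.3,35.7,81.7,0.436,123.6,159.3
Opilioacarus bajacalifornicus,,,,,109.6,,55.0,115.1,0.478,,
Opilioacarus nicaraguensis,male,,,,98.0,,40.7,89.5,0.455,,
Opilioacarus nohbecanus,,,,,83.7,,32.5,75.7,0.429,,
Opilioacarus siankaanensis,female,,,,,,,,0.487,,
Opilioacarus siankaanensis,female,,,,75.9,,32.5,76.2,0.427,,
Opilioacarus siankaanensis,male,,,,76.7,,29.6,73.7,0.401,,
Opilioacarus texanus,,,,,72.7,,26.9,67.6,0.397,105.8,
Salfacarus antisirananensis,male,254.8,177.5,432.3,95.6,19415.3,41.7,91.5,0.455,152.0,221.3
Salfacarus antisirananensis,larva,103.9,40.0,143.9,34.7,2218.0,14.2,30.8,0.461,61.8,64.7
Salfacarus kirindiensis,female,259.3,185.2,444.5,104.9,11110.3,32.0,93.5,0.342,142.4,172.7
Salfacarus mahafaliensis,female,278.4,205.7,484.0,123.5,16471.0,41.6,109.5,0.379,170.9,201.4
Salfacarus ranobensis,male,226.0,162.5,388.5,91.0,15294.8,39.6,85.5,0.463,136.6,191.7
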