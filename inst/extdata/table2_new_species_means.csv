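species,IL,CL,BSL,DSL,MDL,HDS,WDS,HBS,WBS,L1,L2,VR,F2AV,AR
Alliphis halleri,469.6,143.5,44.1,100.5,37.7,26.0,25.4,27.2,25.4,11.2,31.5,0.357,415.3,5.4
Glyphtholaspis confusa,1434.7,546.6,168.2,378.4,136.0,90.7,77.2,99.6,81.9,46.4,114.4,0.406,5867.8,5.74
Parasitus coleoptratorum DN,1280.5,511.6,171.3,340.3,147.3,110.9,85.7,118.6,95.4,38.4,139.0,0.276,4762.3,4.46
Parasitus fucorum DN,1074.3,358.5,121.7,236.8,96.6,83.2,65.3,89.2,70.0,29.8,89.1,0.334,3145.2,4.16
Parasitus lunaris DN,628.1,359.8,117.5,242.3,120.6,62.0,54.5,68.8,61.3,23.1,114.5,0.202,1305.3,5.5
Polyaspis n.sp. DN,846.4,366.6,127.5,239.1,130.4,50.8,48.6,49.5,49.5,23.8,119.2,0.199,938.0,7.31
Uropoda orbicularis DN,682.0,272.3,83.1,189.4,23.4,13.8,14.7,28.3,27.2,8.9,19.4,0.458,741.6,12.93
Veigaia nemorensis (new),678.4,475.4,166.9,308.5,152.4,68.1,61.4,68.6,59.3,33.5,152.6,0.22,1824.2,6.95
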