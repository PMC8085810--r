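habitat,k,n,direction,printed_band
Bumblebees,3,8,Over,<=0.05
Other Hymenoptera,1,3,Over,ns
Scarabaeid or ground beetles,1,7,under,ns
Other insects,1,7,under,ns
Mammals or their nests,3,18,under,ns
Birds or their nests,1,10,under,ns
Seashore,1,14,under,<0.1
Arable grassland,2,12,under,ns
"Leaf litter, mosses",4,17,Over,ns
Houseplant/greenhouse soil,0,4,under,<0.1
"Hay, straw, grain",1,7,under,ns
Compost (rotting vegetation),2,12,under,ns
"Manure, dung, sewage",1,11,under,ns
Corpses/sexton-beetles,0,7,under,<0.06
Fungi (including mushroom beds),0,7,under,<0.06
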