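species,stage_sex,DSL,BSL,BBSL,CL,MDL,F2AV,L1,L2,VR,HDS,HBS,HBBS,rough,ref
Australothyrus ocellatus,female,,,,,,,,,0.23,,,,,Van der Hammen 1983
Hammenius grandjeani gressitti,male,,,,,,,,,0.275,,,,1,Lehtinen 1981
Hammenius insularis,male,,,,,,,,,0.275,,,,1,Lehtinen 1981
Hammenius (Leiothyrus) holthuisi,male,,,,,,,,,0.193,,,,,Van der Hammen 1983
Hammenius (Leiothyrus) nitidissimus,female,,,,,,,,,0.251,,,,1,Lehtinen 1981
Hammenius (Thonius) longipes,male,,,,,,,,,0.195,,,,1,Lehtinen 1981
Hammenius (Thonius) mendi,male,,,,,,,,,0.283,,,,,Lehtinen 1981
Hammenius (Thonius) montanus,male,,,,,,,,,0.227,,,,,Van der Hammen 1983
Haplothyrus hyatti,male,,,,,,,,,0.226,,,,,Lehtinen 1981
Haplothyrus sp. BMNH,DN,,,,,,,,,0.206,,,,,Lehtinen 1981
Lindothyrus rubellus,adult,,,,,,,,,0.325,,,,,Lehtinen 1981
Diplothyrus lecorrei,female,327.2,346.0,294.4,967.6,265.4,4551.8,51.6,253.2,0.204,104.7,140.0,173.7,,Klompen 2010
Diplothyrus lehtineni,female,,,,,107.5,,29.2,94.6,0.308,,,,,Vazquez et al. 2014
Diplothyrus lehtineni,male,303.0,222.7,,,168.1,,45.7,158.3,0.289,100.2,134.0,,,Vazquez et al. 2014
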