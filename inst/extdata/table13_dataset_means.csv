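measure,mean
IL,676.0
CL,285.4
MDL,87.4
F2AV,1601.4
CL_IL,42.3
MDL_IL,12.7
MDL_CL,29.3
F2AV_IL,2.09
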