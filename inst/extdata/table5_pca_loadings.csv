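variable,PC1,PC2,PC3
DSL,-0.5475885,0.8343956,-0.06269695
MDL,-0.5947336,-0.335407,0.73061218
HDS,-0.5885906,-0.4373628,-0.67990804
sd,1.6189,0.5543,0.26846
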