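id,guild,group,trophic_role
P01,plant,NA,NA
P02,plant,NA,NA
P03,plant,NA,NA
P04,plant,NA,NA
P05,plant,NA,NA
P06,plant,NA,NA
P07,plant,NA,NA
P08,plant,NA,NA
A01,pollinator,NA,visitor
A02,pollinator,NA,visitor
A03,pollinator,NA,visitor
A04,pollinator,NA,visitor
A05,pollinator,NA,visitor
A06,pollinator,NA,visitor
A07,pollinator,NA,visitor
A08,pollinator,NA,visitor
A09,pollinator,NA,parasitoid
A10,pollinator,NA,visitor
A11,pollinator,NA,visitor
A12,pollinator,NA,hyper_parasitoid
A13,pollinator,NA,visitor
A14,pollinator,NA,visitor
A15,pollinator,NA,parasitoid
A16,pollinator,NA,visitor
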