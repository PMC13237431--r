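(Propithecus_coquereli:0.090,(Carlito_syrichta:0.080,(Callithrix_jacchus:0.050,((Macaca_fascicularis:0.015,Rhinopithecus_roxellana:0.015)Cercopithecidae:0.025,((((Homo_sapiens:0.008,(Pan_troglodytes:0.004,Pan_paniscus:0.004)Pan:0.004)HomoPan:0.004,Gorilla_gorilla:0.012)Homininae:0.008,(Pongo_abelii:0.006,Pongo_pygmaeus:0.006)Pongo:0.014)Hominidae:0.008,((Hylobates_agilis:0.008,Nomascus_leucogenys:0.008)HylNom:0.004,(Hoolock_leuconedys:0.008,Symphalangus_syndactylus:0.008)HooSym:0.004)Hylobatidae:0.016)Hominoidea:0.012)Catarrhini:0.010)Simiiformes:0.015)Haplorhini:0.010)Primates;
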