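(sifaka_HCAR23|Propithecus_coquereli:1,(tarsier_HCAR23|Carlito_syrichta:1,(marmoset_HCAR23|Callithrix_jacchus:1,((macaque_HCAR23|Macaca_fascicularis:1,snubnosed_HCAR23|Rhinopithecus_roxellana:1):1,(((((human_HCAR2|Homo_sapiens:1,(chimp_HCAR2|Pan_troglodytes:1,bonobo_HCAR2|Pan_paniscus:1):1):1,gorilla_HCAR2|Gorilla_gorilla:1):1,((human_HCAR3|Homo_sapiens:1,(chimp_HCAR3|Pan_troglodytes:1,bonobo_HCAR3|Pan_paniscus:1):1):1,gorilla_HCAR3|Gorilla_gorilla:1):1):1,((pongo_abelii_HCAR2like|Pongo_abelii:1,pongo_pygmaeus_HCAR2like|Pongo_pygmaeus:1):1,(pongo_abelii_HCAR3like|Pongo_abelii:1,pongo_pygmaeus_HCAR3like|Pongo_pygmaeus:1):1):1):1,((siamang_HCAR2like|Symphalangus_syndactylus:1,(hylobates_single|Hylobates_agilis:1,nomascus_single|Nomascus_leucogenys:1):1):1,(siamang_HCAR3like|Symphalangus_syndactylus:1,(hoolock_copy1|Hoolock_leuconedys:1,hoolock_copy2|Hoolock_leuconedys:1):1):1):1):1):1):1):1):1;
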