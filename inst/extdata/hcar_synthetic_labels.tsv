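id	species	group
human_HCAR2	Homo_sapiens	GROUP_A
chimp_HCAR2	Pan_troglodytes	GROUP_A
bonobo_HCAR2	Pan_paniscus	GROUP_A
gorilla_HCAR2	Gorilla_gorilla	GROUP_A
human_HCAR3	Homo_sapiens	GROUP_B
chimp_HCAR3	Pan_troglodytes	GROUP_B
bonobo_HCAR3	Pan_paniscus	GROUP_B
gorilla_HCAR3	Gorilla_gorilla	GROUP_B
pongo_abelii_HCAR2like	Pongo_abelii	QUERY
pongo_pygmaeus_HCAR2like	Pongo_pygmaeus	QUERY
pongo_abelii_HCAR3like	Pongo_abelii	QUERY
pongo_pygmaeus_HCAR3like	Pongo_pygmaeus	QUERY
siamang_HCAR2like	Symphalangus_syndactylus	QUERY
hylobates_single	Hylobates_agilis	QUERY
nomascus_single	Nomascus_leucogenys	QUERY
siamang_HCAR3like	Symphalangus_syndactylus	QUERY
hoolock_copy1	Hoolock_leuconedys	QUERY
hoolock_copy2	Hoolock_leuconedys	QUERY
macaque_HCAR23	Macaca_fascicularis	QUERY
snubnosed_HCAR23	Rhinopithecus_roxellana	QUERY
marmoset_HCAR23	Callithrix_jacchus	QUERY
tarsier_HCAR23	Carlito_syrichta	QUERY
sifaka_HCAR23	Propithecus_coquereli	QUERY
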