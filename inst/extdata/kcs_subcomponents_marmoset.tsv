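Genus	mcode_status	diff_metab	degree_bb	degree_bm	hilo_bb	hilo_bm
Clostridium_sensu_stricto_1	0	7	1	15	0	3
Alloprevotella	5	0	12	0	3	0
Parabacteroides	5	0	13	0	0	0
Flavonifractor	5	0	12	0	0	0
Prevotella	10	0	7	0	0	0
Hafnia-Obesumbacterium	0	6	1	7	0	3
Paraprevotella	5	0	11	0	0	0
Blautia	10	0	2	0	3	0
Bifidobacterium	5	0	9	0	0	0
Bacteroides	5	0	8	1	0	0
Barnesiella	5	0	8	0	0	0
Colidextribacter	5	0	8	0	0	0
Muribaculaceae	5	0	5	0	3	0
Syntrophococcus	5	0	4	0	0	0
Peptococcus	5	0	3	0	0	0
Olsenella	0	1	3	1	0	3
[Ruminococcus]_gnavus_group	0	0	3	4	0	0
Coprobacter	0	0	4	0	3	0
Megasphaera	0	0	2	0	3	0
Coriobacterium	0	0	2	0	3	0
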