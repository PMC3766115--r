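taxgroup_id	phylum	genomes	sites	published_sites_per_genome	regulogs	genes	published_genes_per_genome
Lactobacillaceae	Firmicutes	15	581	39	39	1074	72
Streptococcaceae	Firmicutes	15	400	27	29	881	59
Bacillales	Firmicutes	11	668	61	39	1525	139
Staphylococcaceae	Firmicutes	7	288	41	30	647	92
Clostridiaceae	Firmicutes	20	958	48	40	2036	102
Bacteroidaceae	Bacteroidae	11	84	7.6	2	334	30
Chlorobiales	Chlorobia	11	73	6.6	6	263	24
Corynebacteriaceae	Actinobacteria	8	80	10	13	194	24
Mycobacteriaceae	Actinobacteria	9	131	15	12	247	27
Cyanobacteria	Cyanobacteria	14	86	6.1	11	150	11
Chloroflexi	Chloroflexi	5	98	20	17	300	60
Deinococcus-Thermus	Deinococcus-Thermus	5	64	13	13	221	44
Thermotogales	Thermotogae	11	88	8.0	13	379	34
Desulfovibrionales	Proteobacteria/Delta	10	78	7.8	9	159	16
Caulobacterales	Proteobacteria/Alpha	4	36	9.0	8	70	18
Rhodobacterales	Proteobacteria/Alpha	15	182	12	13	443	30
Rhizobiales	Proteobacteria/Alpha	15	221	15	11	486	32
Burkholderia	Proteobacteria/Beta	8	127	16	9	319	40
Ralstonia	Proteobacteria/Beta	6	66	11	10	173	29
Enterobacteriales	Proteobacteria/Gamma	12	188	16	18	601	50
Pasteurellales	Proteobacteria/Gamma	9	112	12	11	258	29
Vibrionales	Proteobacteria/Gamma	10	202	20	17	533	53
Pseudomonadaceae	Proteobacteria/Gamma	8	92	12	9	248	31
Shewanellaceae	Proteobacteria/Gamma	16	291	18	15	910	57
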