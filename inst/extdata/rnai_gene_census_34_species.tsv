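genome_id	kingdom	phylum	subphylum	argonaute_genes	rdrp_genes
Methanocaldococcus_jannaschii_DSM_2661	Archaea	Euryarchaeota	N/D	1	0
Pyrococcus_furiosus_DSM_3638	Archaea	Crenarchaeota	N/D	1	0
Aquifex_aeolicus_VF5	Bacteria	Aquificae	N/D	1	0
Aspergillus_fumigatus_Af293	Fungi	Ascomycota	Pezizomycotina	2	2
Aspergillus_nidulans	Fungi	Ascomycota	Pezizomycotina	1	2
Botrytis_cinerea	Fungi	Ascomycota	Pezizomycotina	2	2
Coccidioides_immitis_RS	Fungi	Ascomycota	Pezizomycotina	3	3
Colletotrichum_graminicola_M1.001	Fungi	Ascomycota	Pezizomycotina	2	3
Fusarium_graminearum	Fungi	Ascomycota	Pezizomycotina	2	5
Fusarium_oxysporum	Fungi	Ascomycota	Pezizomycotina	5	5
Histoplasma_capsulatum_H88	Fungi	Ascomycota	Pezizomycotina	2	3
Magnaporthe_oryzae_70-15	Fungi	Ascomycota	Pezizomycotina	3	3
Mycosphaerella_graminicola	Fungi	Ascomycota	Pezizomycotina	4	2
Neurospora_crassa	Fungi	Ascomycota	Pezizomycotina	2	3
Podospora_anserina	Fungi	Ascomycota	Pezizomycotina	2	4
Candida_albicans	Fungi	Ascomycota	Saccharomycotina	1	0
Schizosaccharomyces_pombe	Fungi	Ascomycota	Taphrinomycotina	1	1
Heterobasidion_irregulare_TC_32-1	Fungi	Basidiomycota	Agaricomycotina	7	7
Laccaria_bicolor	Fungi	Basidiomycota	Agaricomycotina	6	6
Phanerochaete_chrysosporium	Fungi	Basidiomycota	Agaricomycotina	6	8
Serpula_lacrymans	Fungi	Basidiomycota	Agaricomycotina	6	6
Cryptococcus_neoformans_var._grubii_H99	Fungi	Basidiomycota	Agaricomycotina	1	1
Melampsora_laricis-populina	Fungi	Basidiomycota	Pucciniomycotina	2	5
Puccinia_graminis	Fungi	Basidiomycota	Pucciniomycotina	2	5
Allomyces_macrogynus	Fungi	Blastocladiomycota	N/D	8	0
Batrachochytrium_dendrobatidis_JAM81	Fungi	Chytridiomycota	N/D	2	0
Phycomyces_blakesleeanus	Fungi	Zygomycota	Mucoromycotina	2	4
Rhizopus_oryzae	Fungi	Zygomycota	Mucoromycotina	2	5
Phytophthora_infestans	Chromista	Oomycota	Oomycotina	5	1
Arabidopsis_thaliana	Viridiplantae	Streptophyta	N/D	14	6
Oryza_sativa	Viridiplantae	Streptophyta	N/D	25	6
Drosophila_melanogaster	Metazoa	Arthropoda	N/D	12	0
Caenorhabditis_elegans	Metazoa	Nematoda	N/D	31	4
Homo_sapiens	Metazoa	Chordata	Craniata	17	0
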