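name	node_role	min_age	max_age	evidence	taxa
Diatoms stem node (1)	stem		397	secondary	Anomoeoneis_sculpta;Cymbella_aspera;Cymbella_helvetica;Cymbella_mexicana;Cymbella_proxima;Cymbella_tumida;Cymbopleura_inaequalis;Cymbopleura_naviculiformis;Didymosphenia_dentata;Didymosphenia_siberica;Gomphoneis_minuta;Gomphonema_clevei;Mayamaea_atomus;Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis;Sellaphora_blackfordensis;Cocconeis_stauroneiformis;Fragilaria_bidens;Pteroncola_inane;Nanofrustulum_shiloi;Opephora_sp;Pseudostaurosira_brevistriata;Licmophora_paradoxa;Tabularia_laevis;Pseudohimantidium_pacificum;Diatoma_moniliforme;Thalassiothrix_longissima;Dimeregramma_minor;Rhaphoneis_sp;Cyclophora_tenuis;Plagiostriata_goreensis;Grammatophora_marina;Hyalosira_delicatula;Hyalosira_tropicalis;Rhabdonema_minutum;Eunotogramma_laevis;Cymatosira_belgica;Odontella_sinensis;Cyclotella_meneghiniana;Stephanodiscus_sp;Skeletonema_tropicum;Thalassiosira_nordenskioeldii;Aulacoseira_granulata;Stephanopyxis_turris;Hyalodiscus_scoticus
Diatoms stem node (1)	stem	190		fossil	Anomoeoneis_sculpta;Cymbella_aspera;Cymbella_helvetica;Cymbella_mexicana;Cymbella_proxima;Cymbella_tumida;Cymbopleura_inaequalis;Cymbopleura_naviculiformis;Didymosphenia_dentata;Didymosphenia_siberica;Gomphoneis_minuta;Gomphonema_clevei;Mayamaea_atomus;Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis;Sellaphora_blackfordensis;Cocconeis_stauroneiformis;Fragilaria_bidens;Pteroncola_inane;Nanofrustulum_shiloi;Opephora_sp;Pseudostaurosira_brevistriata;Licmophora_paradoxa;Tabularia_laevis;Pseudohimantidium_pacificum;Diatoma_moniliforme;Thalassiothrix_longissima;Dimeregramma_minor;Rhaphoneis_sp;Cyclophora_tenuis;Plagiostriata_goreensis;Grammatophora_marina;Hyalosira_delicatula;Hyalosira_tropicalis;Rhabdonema_minutum;Eunotogramma_laevis;Cymatosira_belgica;Odontella_sinensis;Cyclotella_meneghiniana;Stephanodiscus_sp;Skeletonema_tropicum;Thalassiosira_nordenskioeldii;Aulacoseira_granulata;Stephanopyxis_turris;Hyalodiscus_scoticus
Diatoms crown node (2)	crown	160	267	secondary	Anomoeoneis_sculpta;Cymbella_aspera;Cymbella_helvetica;Cymbella_mexicana;Cymbella_proxima;Cymbella_tumida;Cymbopleura_inaequalis;Cymbopleura_naviculiformis;Didymosphenia_dentata;Didymosphenia_siberica;Gomphoneis_minuta;Gomphonema_clevei;Mayamaea_atomus;Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis;Sellaphora_blackfordensis;Cocconeis_stauroneiformis;Fragilaria_bidens;Pteroncola_inane;Nanofrustulum_shiloi;Opephora_sp;Pseudostaurosira_brevistriata;Licmophora_paradoxa;Tabularia_laevis;Pseudohimantidium_pacificum;Diatoma_moniliforme;Thalassiothrix_longissima;Dimeregramma_minor;Rhaphoneis_sp;Cyclophora_tenuis;Plagiostriata_goreensis;Grammatophora_marina;Hyalosira_delicatula;Hyalosira_tropicalis;Rhabdonema_minutum;Eunotogramma_laevis;Cymatosira_belgica;Odontella_sinensis;Cyclotella_meneghiniana;Stephanodiscus_sp;Skeletonema_tropicum;Thalassiosira_nordenskioeldii;Aulacoseira_granulata;Stephanopyxis_turris;Hyalodiscus_scoticus
Mediophyceae stem node (3)	stem		267		Eunotogramma_laevis;Cymatosira_belgica;Odontella_sinensis;Cyclotella_meneghiniana;Stephanodiscus_sp;Skeletonema_tropicum;Thalassiosira_nordenskioeldii
Mediophyceae stem node (3)	stem	110		fossil	Eunotogramma_laevis;Cymatosira_belgica;Odontella_sinensis;Cyclotella_meneghiniana;Stephanodiscus_sp;Skeletonema_tropicum;Thalassiosira_nordenskioeldii
Bacillariophyceae crown node (4)	crown	96.5	204	secondary	Anomoeoneis_sculpta;Cymbella_aspera;Cymbella_helvetica;Cymbella_mexicana;Cymbella_proxima;Cymbella_tumida;Cymbopleura_inaequalis;Cymbopleura_naviculiformis;Didymosphenia_dentata;Didymosphenia_siberica;Gomphoneis_minuta;Gomphonema_clevei;Mayamaea_atomus;Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis;Sellaphora_blackfordensis;Cocconeis_stauroneiformis;Fragilaria_bidens;Pteroncola_inane;Nanofrustulum_shiloi;Opephora_sp;Pseudostaurosira_brevistriata;Licmophora_paradoxa;Tabularia_laevis;Pseudohimantidium_pacificum;Diatoma_moniliforme;Thalassiothrix_longissima;Dimeregramma_minor;Rhaphoneis_sp;Cyclophora_tenuis;Plagiostriata_goreensis;Grammatophora_marina;Hyalosira_delicatula;Hyalosira_tropicalis;Rhabdonema_minutum
Core araphids/raphids split (5)	crown	93.8	185	secondary	Fragilaria_bidens;Pteroncola_inane;Nanofrustulum_shiloi;Opephora_sp;Pseudostaurosira_brevistriata;Licmophora_paradoxa;Tabularia_laevis;Pseudohimantidium_pacificum;Diatoma_moniliforme;Thalassiothrix_longissima;Dimeregramma_minor;Rhaphoneis_sp;Anomoeoneis_sculpta;Cymbella_aspera;Cymbella_helvetica;Cymbella_mexicana;Cymbella_proxima;Cymbella_tumida;Cymbopleura_inaequalis;Cymbopleura_naviculiformis;Didymosphenia_dentata;Didymosphenia_siberica;Gomphoneis_minuta;Gomphonema_clevei;Mayamaea_atomus;Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis;Sellaphora_blackfordensis;Cocconeis_stauroneiformis
Raphid pennates crown (6)	crown	70	165	secondary	Anomoeoneis_sculpta;Cymbella_aspera;Cymbella_helvetica;Cymbella_mexicana;Cymbella_proxima;Cymbella_tumida;Cymbopleura_inaequalis;Cymbopleura_naviculiformis;Didymosphenia_dentata;Didymosphenia_siberica;Gomphoneis_minuta;Gomphonema_clevei;Mayamaea_atomus;Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis;Sellaphora_blackfordensis;Cocconeis_stauroneiformis
Pinnularia stem node (7)	stem		100	secondary	Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis
Pinnularia stem node (7)	stem	40		fossil	Pinnularia_acuminata;Pinnularia_altiplanensis;Pinnularia_grunowii;Pinnularia_microstauron;Pinnularia_nodosa;Pinnularia_sp;Pinnularia_subcommutata;Pinnularia_viridiforme;Pinnularia_viridiformis
Didymosphenia crown node (8)	crown		70	geological	Didymosphenia_dentata;Didymosphenia_siberica
Didymosphenia crown node (8)	crown	7.3		fossil	Didymosphenia_dentata;Didymosphenia_siberica
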