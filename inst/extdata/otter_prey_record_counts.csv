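river,year,taxon,n_records
Mopan,2016,Strongylura marina,1
Mopan,2016,Caranx latus,1
Mopan,2016,Centropomus ensiferus,1
Mopan,2016,Chuco intermedius,6
Mopan,2016,Cincelichthys bocourti,1
Mopan,2016,Cribroheros robertsoni,1
Mopan,2016,Mayaheros urophtalmus,2
Mopan,2016,Oreochromis aureus,8
Mopan,2016,Parachromis friedrichsthalii,2
Mopan,2016,Thorichthys aureus,6
Mopan,2016,Thorichthys meeki,5
Mopan,2016,Dormitator maculatus,1
Mopan,2016,Poecilia mexicana,1
Mopan,2016,Catfish,8
Mopan,2016,Potamocarcinus sp,32
Mopan,2016,Unknown Insects,3
Mopan,2016,Unknown Reptile,3
Mopan,2016,Unknown Mammal,1
Mopan,2016,Unknown,8
Pasion,2010,Cribroheros robertsoni,13
Pasion,2010,Maskaheros argenteus,1
Pasion,2010,Mayaheros urophtalmus,5
Pasion,2010,Oreochromis aureus,5
Pasion,2010,Parachromis friedrichsthalii,9
Pasion,2010,Petenia splendida,1
Pasion,2010,Rheoheros lentiginosus,1
Pasion,2010,Rocio octofasciata,2
Pasion,2010,Thorichthys affinis,2
Pasion,2010,Thorichthys meeki,11
Pasion,2010,Thorichthys pasionis,10
Pasion,2010,Vieja bifasciata,3
Pasion,2010,Vieja melanurus,3
Pasion,2010,Ctenopharyngodon idella,7
Pasion,2010,Pterygoplichthys spp,14
Pasion,2010,Mugil cephalus,1
Pasion,2010,Belonesox belizanus,5
Pasion,2010,Poecilia mexicana,3
Pasion,2010,Poecilia petenensis,11
Pasion,2010,Catfish,3
Pasion,2010,Potamocarcinus sp,30
Pasion,2010,Unknown,2
Pasion,2015,Cincelichthys bocourti,1
Pasion,2015,Cribroheros robertsoni,4
Pasion,2015,Mayaheros urophtalmus,5
Pasion,2015,Oreochromis aureus,6
Pasion,2015,Parachromis friedrichsthalii,5
Pasion,2015,Rheoheros lentiginosus,1
Pasion,2015,Rocio octofasciata,1
Pasion,2015,Thorichthys meeki,2
Pasion,2015,Thorichthys pasionis,1
Pasion,2015,Vieja bifasciata,6
Pasion,2015,Vieja melanurus,1
Pasion,2015,Pterygoplichthys spp,36
Pasion,2015,Poecilia mexicana,1
Pasion,2015,Poecilia petenensis,1
Pasion,2015,Catfish,1
Pasion,2015,Unknown Reptile,1
San Pedro,2009,Strongylura hubbsi,3
San Pedro,2009,Astianax fasciatus,9
San Pedro,2009,Cribroheros robertsoni,22
San Pedro,2009,Kihmchithys ufermammi,3
San Pedro,2009,Mayaheros urophtalmus,5
San Pedro,2009,Oreochromis aureus,4
San Pedro,2009,Parachromis friedrichsthalii,1
San Pedro,2009,Thorichthys meeki,10
San Pedro,2009,Thorichthys pasionis,10
San Pedro,2009,Vieja bifasciata,1
San Pedro,2009,Hyporhamphus mexicanus,9
San Pedro,2009,Aractosteus tropicus,1
San Pedro,2009,Pterygoplichthys spp,23
San Pedro,2009,Belonesox belizanus,1
San Pedro,2009,Poecilia mexicana,17
San Pedro,2009,Poecilia petenensis,17
San Pedro,2009,Catfish,3
San Pedro,2015,Astianax fasciatus,1
San Pedro,2015,Chuco intermedius,1
San Pedro,2015,Cincelichthys bocourti,1
San Pedro,2015,Cincelichthys pearsei,1
San Pedro,2015,Cribroheros robertsoni,12
San Pedro,2015,Kihmchithys ufermammi,1
San Pedro,2015,Mayaheros urophtalmus,17
San Pedro,2015,Oreochromis aureus,21
San Pedro,2015,Parachromis friedrichsthalii,4
San Pedro,2015,Petenia splendida,3
San Pedro,2015,Rocio octofasciata,3
San Pedro,2015,Thorichthys affinis,1
San Pedro,2015,Thorichthys meeki,25
San Pedro,2015,Thorichthys pasionis,8
San Pedro,2015,Trichromis salvini,2
San Pedro,2015,Vieja bifasciata,21
San Pedro,2015,Vieja melanurus,8
San Pedro,2015,Ctenopharyngodon idella,5
San Pedro,2015,Eugerres mexicanus,4
San Pedro,2015,Hyporhamphus mexicanus,2
San Pedro,2015,Megalops atlanticus,1
San Pedro,2015,Pterygoplichthys spp,75
San Pedro,2015,Belonesox belizanus,12
San Pedro,2015,Poecilia mexicana,24
San Pedro,2015,Poecilia petenensis,26
San Pedro,2015,Catfish,4
San Pedro,2015,Potamocarcinus sp,3
San Pedro,2015,Macrobrachium sp,1
San Pedro,2015,Unknown,2
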