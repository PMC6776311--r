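taxon,family,ftl,max_total_length_mm,ftl_source
Strongylura hubbsi,Belonidae,4.2,350,synthetic lookup; piscivorous needlefish
Strongylura marina,Belonidae,4.4,640,synthetic lookup; piscivorous needlefish
Caranx latus,Carangidae,3.6,800,synthetic lookup; carnivorous jack
Centropomus ensiferus,Centropomidae,4.0,370,synthetic lookup; piscivorous snook
Astianax fasciatus,Characidae,2.9,170,synthetic lookup; omnivorous tetra
Chuco intermedius,Cichlidae,2.4,250,synthetic lookup; detritivorous cichlid
Cincelichthys bocourti,Cichlidae,2.2,280,synthetic lookup; herbivorous cichlid
Cincelichthys pearsei,Cichlidae,2.0,280,synthetic lookup; herbivorous cichlid
Cribroheros robertsoni,Cichlidae,3.1,250,synthetic lookup; invertivorous cichlid
Kihmchithys ufermammi,Cichlidae,2.8,300,synthetic lookup; omnivorous cichlid
Maskaheros argenteus,Cichlidae,NA,350,no trophic estimate available
Mayaheros urophtalmus,Cichlidae,3.3,390,synthetic lookup; carnivorous cichlid
Oreochromis aureus,Cichlidae,2.1,450,synthetic lookup; herbivorous tilapia
Parachromis friedrichsthalii,Cichlidae,3.8,280,synthetic lookup; piscivorous cichlid
Petenia splendida,Cichlidae,4.0,500,synthetic lookup; piscivorous cichlid
Rheoheros lentiginosus,Cichlidae,2.9,150,synthetic lookup; invertivorous cichlid
Rocio octofasciata,Cichlidae,3.2,220,synthetic lookup; invertivorous cichlid
Thorichthys affinis,Cichlidae,3.0,140,synthetic lookup; invertivorous cichlid
Thorichthys aureus,Cichlidae,3.0,160,synthetic lookup; invertivorous cichlid
Thorichthys meeki,Cichlidae,3.1,170,synthetic lookup; invertivorous cichlid
Thorichthys pasionis,Cichlidae,2.9,170,synthetic lookup; invertivorous cichlid
Trichromis salvini,Cichlidae,3.6,220,synthetic lookup; carnivorous cichlid
Vieja bifasciata,Cichlidae,2.3,300,synthetic lookup; herbivorous cichlid
Vieja melanurus,Cichlidae,2.2,350,synthetic lookup; herbivorous cichlid
Ctenopharyngodon idella,Cyprinidae,2.0,1500,synthetic lookup; herbivorous carp
Dormitator maculatus,Eleotridae,2.5,700,synthetic lookup; detritivorous sleeper
Eugerres mexicanus,Gerreidae,3.2,350,synthetic lookup; invertivorous mojarra
Hyporhamphus mexicanus,Hemiramphidae,2.5,250,synthetic lookup; herbivorous halfbeak
Aractosteus tropicus,Lepisosteidae,4.1,1250,synthetic lookup; piscivorous gar
Pterygoplichthys spp,Loricariidae,2.0,500,synthetic lookup; detritivorous armored catfish
Megalops atlanticus,Megalopidae,4.3,2500,synthetic lookup; piscivorous tarpon
Mugil cephalus,Mugilidae,2.1,1000,synthetic lookup; detritivorous mullet
Belonesox belizanus,Poeciliidae,4.2,200,synthetic lookup; piscivorous livebearer
Poecilia mexicana,Poeciliidae,2.2,110,synthetic lookup; algivorous molly
Poecilia petenensis,Poeciliidae,2.2,120,synthetic lookup; algivorous molly
Catfish,"Ariidae, Heptapteridae, Ictaluridae",3.2,400,synthetic lookup; mean of omnivorous catfishes
Potamocarcinus sp,Pseudothelphusidae,2.5,150,synthetic lookup; mean of similar freshwater crabs
Macrobrachium sp,Palaemonidae,NA,250,no trophic estimate available; excluded like crayfish
Unknown Insects,Unknown,NA,NA,unidentified; no trophic estimate
Unknown Reptile,Unknown,NA,NA,unidentified; no trophic estimate
Unknown Mammal,Unknown,NA,NA,unidentified; no trophic estimate
Unknown,Unknown,NA,NA,unidentified; no trophic estimate
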