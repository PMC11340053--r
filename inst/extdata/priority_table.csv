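group,species,ailment,fl,rpl,rop,note
Gedeo,Achyranthes aspera,Jaundice,50.0,0.5,25.0,
Gedeo,Allium sativum,Stomachache,50.0,0.5,25.0,
Gedeo,Allium sativum,Common cold,75.0,0.75,56.0,
Gedeo,Artemisia abyssinica,Bad/evil spirit,66.67,0.67,45.0,
Gedeo,Brucea antidysenterica,Diarrhea,75.0,0.75,56.0,
Gedeo,Celtis africana,Stomachache,50.0,0.5,25.0,
Gedeo,Commelina benghalensis,Skin infection,66.67,0.67,45.0,
Gedeo,Clutia abyssinica,Deep sores /cancer-like ailments,50.0,0.5,25.0,
Gedeo,Cymbopogon citratus,Blood pressure,80.0,0.8,64.0,
Gedeo,Cymbopogon citratus,Abortion,60.0,0.6,36.0,
Gedeo,Datura stramonium,Rabies,66.67,0.67,45.0,
Gedeo,Drynaria volkensii,Swellings,50.0,0.5,25.0,
Gedeo,Drynaria volkensii,Ear infection,50.0,0.5,25.0,
Gedeo,Ekebergia capensis,Diarrhea,66.67,0.67,45.0,
Gedeo,Ekebergia capensis,Stomachache,66.67,0.67,45.0,
Gedeo,Ensete ventricosum,Lightning,66.67,0.67,45.0,
Gedeo,Erythrina abyssinica,Cough,,0.5,25.0,FL missing in source
Gedeo,Galinsoga quadriradiata,Tonsillitis,85.71,0.86,74.0,
Gedeo,Grewia ferruginea,Headache,66.67,0.67,45.0,
Gedeo,Hyparrhenia rufa,Swellings,66.67,0.67,45.0,
Gedeo,Justicia schimperiana,Jaundice,50.0,0.5,25.0,
Gedeo,Lactuca inermis,Anemia,100.0,1.0,100.0,
Gedeo,Lactuca inermis,Stomachache,50.0,0.5,25.0,
Gedeo,Lagenaria siceraria,Amoeba,66.67,0.67,45.0,
Gedeo,Moringa stenopetala,Blood pressure,100.0,1.0,100.0,
Gedeo,Moringa stenopetala,Glandular,50.0,0.5,25.0,
Gedeo,Ocimum gratissimum,Febrile illness,71.43,0.71,51.0,
Gedeo,Coleus igniarius,Stomachache,66.67,0.67,45.0,
Gedeo,Ricinus communis,Swellings,80.0,0.8,64.0,
Gedeo,Syzygium guineense,Pain relief,66.67,0.67,45.0,
Gedeo,Solanecio gigas,Jaundice,53.85,0.54,29.0,
Gedeo,Gymnanthemum auriculiferum,Snake venom,66.67,0.67,45.0,
Gedeo,Withania somnifera,Bad/evil spirit,100.0,1.0,100.0,
Gedeo,Zingiber officinale,Tonsillitis,66.67,0.67,45.0,
Oromo,Vachellia oerfota,Bad/evil spirit,87.5,0.88,77.0,
Oromo,Allium sativum,Common cold,100.0,1.0,100.0,
Oromo,Allium sativum,Typhoid,60.0,0.4,24.0,
Oromo,Allium sativum,Tonsillitis,60.0,0.4,24.0,
Oromo,Aloe macrocarpa,Malaria,62.5,0.62,39.0,
Oromo,Aloe macrocarpa,Typhoid,50.0,0.5,25.0,
Oromo,Albizia gummifera,Dizziness,50.0,0.5,25.0,
Oromo,Brassica carinata,Fever,66.67,0.67,45.0,
Oromo,Carissa spinarum,Bad/evil spirit,66.67,0.67,45.0,
Oromo,Citrus limon,Blood pressure,100.0,1.0,100.0,
Oromo,Rotheca myricoides,Stomachache,75.0,0.5,38.0,
Oromo,Coffea arabica,Sneezing,60.0,0.6,36.0,
Oromo,Ekebergia capensis,Skin infection,50.0,0.5,25.0,
Oromo,Erica arborea,Wound,66.67,0.67,45.0,
Oromo,Eucalyptus globulus,Asthma,77.78,0.78,61.0,
Oromo,Eucalyptus globulus,Common cold,53.85,0.54,29.0,
Oromo,Ficus sycomorus,Tonsillitis,66.67,0.67,45.0,
Oromo,Hagenia abyssinica,Tapeworm,60.0,0.6,36.0,
Oromo,Justicia schimperiana,Jaundice,77.78,0.78,61.0,
Oromo,Phytolacca dodecandra,Abortion,66.67,0.67,45.0,
Oromo,Ocimum lamiifolium,Febrile illness,66.67,0.67,45.0,
Oromo,Ocimum gratissimum,Febrile illness,87.5,0.75,66.0,
Oromo,Searsia natalensis,Autism,50.0,0.5,25.0,decimal point missing in source
Oromo,Ricinus communis,Swellings,100.0,1.0,100.0,
Oromo,Solanum incanum,Nasal bleeding,80.0,0.8,64.0,
Oromo,Schinus molle,Jaundice,100.0,1.0,100.0,
Oromo,Stephania abyssinica,Gonorrhea,50.0,0.5,25.0,
Oromo,Withania somnifera,Bad/evil spirit,66.67,0.6,36.0,ROP != RPL*FL at printed precision
Oromo,Ziziphus spina-christi,Gonorrhea,50.0,0.5,25.0,
Oromo,Ziziphus spina-christi,Bad/evil spirit,50.0,0.5,25.0,
Sidama,Achyranthes aspera,Headache,50.0,0.5,25.0,
Sidama,Albizia gummifera,Dizziness,57.14,0.57,33.0,
Sidama,Allium sativum,Fever,50.0,0.38,19.0,
Sidama,Allium sativum,Typhoid,87.5,0.75,66.0,
Sidama,Antiaris toxicaria,Rabies,100.0,1.0,100.0,
Sidama,Balanites aegyptiaca,Amoeba,75.0,0.75,56.0,
Sidama,Balanites aegyptiaca,Diarrhea,75.0,0.75,56.0,
Sidama,Brucea antidysenterica,Gonorrhea,100.0,1.0,100.0,
Sidama,Carica papaya,Malaria,100.0,0.86,86.0,
Sidama,Carissa spinarum,Diarrhea,66.67,0.67,45.0,
Sidama,Catha edulis,Gonorrhea,71.43,0.71,51.0,
Sidama,Cinnamomum verum,Asthma,66.67,0.67,45.0,
Sidama,Cinnamomum verum,Common cold,66.67,0.67,45.0,
Sidama,Clutia abyssinica,Diarrhea,50.0,0.5,25.0,
Sidama,Echinops kebericho,Common cold,100.0,1.0,100.0,
Sidama,Echinops kebericho,Febrile illness,100.0,1.0,100.0,
Sidama,Echinops kebericho,Headache,75.0,0.75,56.0,
Sidama,Ekebergia capensis,Amoeba,60.0,0.6,36.0,
Sidama,Eucalyptus globulus,Common cold,60.0,0.54,29.0,ROP != RPL*FL at printed precision
Sidama,Lagenaria siceraria,Jaundice,60.0,0.6,36.0,
Sidama,Melia azedarach,Malaria,75.0,0.62,47.0,
Sidama,Moringa stenopetala,Glandular,66.67,0.67,45.0,
Sidama,Ocimum jamesii,Febrile illness,100.0,1.0,100.0,
Sidama,Afrocarpus falcatus,Gonorrhea,100.0,1.0,100.0,
Sidama,Searsia natalensis,Glandular,83.33,0.83,69.0,
Sidama,Ricinus communis,Swellings,100.0,1.0,100.0,
Sidama,Ricinus communis,Tonsillitis,66.67,0.33,22.0,
Sidama,Ruta chalepensis,Typhoid,57.14,0.57,33.0,
Sidama,Searsia natalensis,Snake venom,100.0,1.0,100.0,
Sidama,Stephania abyssinica,Jaundice,50.0,0.5,25.0,
Sidama,Stephania abyssinica,Glandular,50.0,0.5,25.0,
Sidama,Syzygium guineense,Amoeba,50.0,0.5,25.0,
Sidama,Syzygium guineense,Bad/evil spirit,50.0,0.5,25.0,
Sidama,Taverniera abyssinica,Febrile illness,66.67,0.67,45.0,
Sidama,Urtica simensis,Bad/evil spirit,83.33,0.83,69.0,
Sidama,Gymnanthemum amygdalinum,Amoeba,61.54,0.62,38.0,
Sidama,Gymnanthemum amygdalinum,Malaria,53.85,0.54,29.0,
Sidama,Withania somnifera,Bad/evil spirit,75.0,0.75,56.0,
Sidama,Zingiber officinale,Tonsillitis,100.0,0.83,83.0,
Sidama,Zingiber officinale,Malaria,50.0,0.5,25.0,
Sidama,Zingiber officinale,Wound,50.0,0.5,25.0,
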