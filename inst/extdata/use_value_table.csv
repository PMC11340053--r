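species,group,fc,ur,nu,uv_printed,uv_consistent
Vachellia oerfota,Oromo,8,8,2,0.127,1
Achyranthes aspera,Gedeo,4,6,5,0.1,1
Achyranthes aspera,Oromo,7,7,5,0.111,1
Achyranthes aspera,Sidama,4,7,6,0.111,1
Ajuga integrifolia,Sidama,10,12,5,0.19,1
Albizia gummifera,Gedeo,20,47,20,0.75,1
Albizia gummifera,Oromo,6,10,7,0.159,1
Albizia gummifera,Sidama,7,13,8,0.206,1
Allium sativum,Gedeo,4,11,7,0.18,0
Allium sativum,Oromo,5,12,6,0.19,1
Allium sativum,Sidama,8,23,9,0.365,1
Aloe macrocarpa,Oromo,16,38,14,0.603,1
Aloe vera,Sidama,5,6,4,0.095,1
Argemone mexicana,Oromo,5,5,4,0.079,1
Artemisia abyssinica,Gedeo,6,11,6,0.18,0
Asparagus africanus,Gedeo,10,13,7,0.21,1
Asparagus africanus,Oromo,6,6,5,0.095,1
Balanites aegyptiaca,Sidama,4,7,3,0.111,1
Bersama abyssinica,Gedeo,4,5,4,0.08,1
Calpurnia aurea,Gedeo,19,31,13,0.49,1
Calpurnia aurea,Oromo,11,14,9,0.222,1
Calpurnia aurea,Sidama,4,5,5,0.079,1
Carica papaya,Oromo,4,7,6,0.111,1
Carica papaya,Sidama,7,10,4,0.159,1
Carissa spinarum,Oromo,6,6,3,0.095,1
Catha edulis,Sidama,7,9,4,0.143,1
Celtis africana,Gedeo,10,18,11,0.29,1
Cinnamomum verum,Sidama,3,5,3,0.079,1
Citrus limon,Oromo,6,11,5,0.175,1
Clutia abyssinica,Oromo,6,7,6,0.111,1
Clutia abyssinica,Sidama,6,6,4,0.095,1
Coffea arabica,Gedeo,9,12,8,0.19,1
Coffea arabica,Oromo,5,9,5,0.143,1
Croton macrostachyus,Gedeo,28,80,21,1.32,0
Croton macrostachyus,Oromo,21,48,22,0.8,0
Croton macrostachyus,Sidama,17,36,15,0.6,0
Cucumis prophetarum,Sidama,14,20,9,0.317,1
Cymbopogon citratus,Gedeo,5,15,9,0.24,1
Datura stramonium,Oromo,6,6,3,0.095,1
Dodonaea viscosa subsp. angustifolia,Oromo,8,9,6,0.143,1
Drynaria volkensii,Gedeo,4,6,4,0.1,1
Echinops kebericho,Sidama,4,10,4,0.159,1
Ehretia cymosa,Sidama,5,5,5,0.079,1
Ekebergia capensis Sparrm,Gedeo,5,9,5,0.14,1
Ekebergia capensis Sparrm,Oromo,6,14,10,0.222,1
Ekebergia capensis Sparrm,Sidama,15,20,8,0.317,1
Ensete ventricosum,Gedeo,6,7,4,0.11,1
Erythrina abyssinica,Gedeo,6,10,8,0.16,1
Erythrina abyssinica,Oromo,6,6,6,0.095,1
Eucalyptus globulus,Gedeo,5,7,5,0.11,1
Eucalyptus globulus,Oromo,9,16,5,0.254,1
Eucalyptus globulus,Sidama,9,20,11,0.317,1
Galinsoga quadriradiata,Gedeo,7,9,4,0.14,1
Grewia ferruginea,Gedeo,5,9,8,0.14,1
Hagenia abyssinica,Oromo,5,7,5,0.111,1
Justicia schimperiana,Gedeo,6,8,5,0.13,1
Justicia schimperiana,Oromo,9,11,4,0.175,1
Justicia schimperiana,Sidama,8,9,5,0.143,1
Kalanchoe petitiana,Sidama,6,7,5,0.111,1
Lactuca inermis,Gedeo,4,9,3,0.14,1
Lagenaria siceraria,Gedeo,3,5,4,0.08,1
Lagenaria siceraria,Sidama,5,6,3,0.095,1
Linum usitatissimum,Sidama,4,8,5,0.127,1
Maesa lanceolata,Gedeo,7,9,7,0.14,1
Melia azedarach,Gedeo,3,6,6,0.1,1
Melia azedarach,Oromo,11,16,11,0.254,1
Melia azedarach,Sidama,8,15,9,0.238,1
Millettia ferruginea,Gedeo,6,12,10,0.19,1
Momordica boivinii,Sidama,7,7,6,0.111,1
Moringa stenopetala,Gedeo,4,9,5,0.14,1
Moringa stenopetala,Oromo,13,25,14,0.397,1
Moringa stenopetala,Sidama,3,5,2,0.079,1
Nigella sativa,Gedeo,3,7,7,0.11,1
Nigella sativa,Oromo,7,12,10,0.19,1
Ocimum jamesii,Sidama,5,5,1,0.079,1
Ocimum lamiifolium,Gedeo,3,6,6,0.1,1
Ocimum gratissimum,Gedeo,7,15,6,0.24,1
Ocimum gratissimum,Oromo,8,14,6,0.222,1
Olea europaea subsp. cuspidata,Gedeo,9,11,6,0.18,0
Olea europaea subsp. cuspidata,Oromo,11,25,18,0.397,1
Olinia rochetiana,Oromo,12,13,8,0.206,1
Phytolacca dodecandra,Gedeo,3,5,5,0.08,1
Phytolacca dodecandra,Sidama,9,14,7,0.222,1
Coleus igniarius,Sidama,8,13,6,0.206,1
Afrocarpus falcatus,Gedeo,16,26,10,0.41,1
Psidium guajava,Oromo,3,6,4,0.095,1
Psydrax schimperianus,Oromo,5,7,5,0.111,1
Searsia glutinosa,Sidama,12,13,3,0.206,1
Ricinus communis,Gedeo,5,9,4,0.14,1
Ricinus communis,Sidama,3,7,5,0.111,1
Rotheca myricoides,Sidama,11,16,7,0.254,1
Rubus steudneri,Oromo,4,8,8,0.127,1
Ruta chalepensis,Gedeo,15,28,17,0.44,1
Ruta chalepensis,Oromo,9,19,13,0.302,1
Ruta chalepensis,Sidama,14,21,8,0.333,1
Schinus molle,Oromo,4,6,3,0.095,1
Searsia natalensis,Sidama,7,7,1,0.111,1
Sida schimperiana,Gedeo,4,6,6,0.1,1
Solanecio gigas,Gedeo,13,20,10,0.32,1
Solanum incanum,Oromo,5,9,3,0.143,1
Solanum incanum,Sidama,6,6,3,0.095,1
Solanum marginatum,Oromo,5,7,6,0.111,1
Stephania abyssinica,Sidama,6,6,2,0.095,1
Syzygium guineense,Gedeo,4,6,5,0.1,1
Syzygium guineense,Oromo,5,6,5,0.095,1
Syzygium guineense,Sidama,4,6,4,0.095,1
Vepris nobilis,Oromo,4,6,5,0.095,1
Trigonella foenum-graecum,Gedeo,4,12,10,0.19,1
Urtica simensis,Sidama,6,6,2,0.095,1
Gymnanthemum amygdalinum,Gedeo,11,17,8,0.27,1
Gymnanthemum amygdalinum,Oromo,21,34,15,0.54,1
Gymnanthemum amygdalinum,Sidama,13,25,6,0.397,1
Vicia faba,Gedeo,6,6,1,0.1,1
Vicia faba,Sidama,10,10,1,0.159,1
Withania somnifera,Oromo,5,8,5,0.127,1
Withania somnifera,Sidama,8,10,3,0.159,1
Zingiber officinale,Gedeo,3,7,5,0.11,1
Zingiber officinale,Oromo,8,16,11,0.254,1
Zingiber officinale,Sidama,12,46,13,0.7,1
Ziziphus spina-christi,Oromo,4,10,8,0.159,1
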