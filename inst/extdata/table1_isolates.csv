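plant,location,tissue,morphospecies,genus,phylum,class_name,colony_count
Agathophora alopecuroides,PAWD,leaf,Aspergillus sp.1,Aspergillus,Ascomycota,Eurotiomycetes,1
Agathophora alopecuroides,PAWD,stem,Chaetomium sp.,Chaetomium,Ascomycota,Sordariomycetes,1
Agathophora alopecuroides,PAWD,root,Eurotium sp.,Eurotium,Ascomycota,Eurotiomycetes,1
Agathophora alopecuroides,PAWD,leaf,Trichosporon sp.,Trichosporon,Basidiomycota,Tremellomycetes,1
Anabasis setifera,PAWD,leaf,Aspergillus sp.2,Aspergillus,Ascomycota,Eurotiomycetes,1
Anabasis setifera,PAWD,stem,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,1
Anabasis setifera,PAWD,root,Aspergillus sp.4,Aspergillus,Ascomycota,Eurotiomycetes,1
Anabasis setifera,PAWD,leaf,Fusarium sp.1,Fusarium,Ascomycota,Sordariomycetes,1
Anabasis setifera,PAWD,stem,Penicillium sp.1,Penicillium,Ascomycota,Eurotiomycetes,1
Anabasis setifera,PAWD,root,Penicillium sp.2,Penicillium,Ascomycota,Eurotiomycetes,1
Anabasis setifera,PAWD,leaf,Phragmocamarosporium sp.1,Phragmocamarosporium,Ascomycota,Dothideomycetes,1
Anabasis setifera,PAWD,stem,Neocosmospora sp.,Neocosmospora,Ascomycota,Sordariomycetes,1
Halocnemum strobitaceum,PAWD,leaf,Aspergillus sp.5,Aspergillus,Ascomycota,Eurotiomycetes,1
Halocnemum strobitaceum,PAWD,stem,Aspergillus sp.6,Aspergillus,Ascomycota,Eurotiomycetes,1
Halocnemum strobitaceum,PAWD,leaf,Phaeocremonium sp.,Phaeocremonium,Ascomycota,Sordariomycetes,1
Halocnemum strobitaceum,PAWD,stem,Talaromyces sp.,Talaromyces,Ascomycota,Eurotiomycetes,1
Lantana camara L,NCAH,flower,Eurotium sp.,Eurotium,Ascomycota,Eurotiomycetes,1
Lantana camara L,NCAH,stem,Penicillium sp.3,Penicillium,Ascomycota,Eurotiomycetes,1
Lantana camara L,NCAH,flower,Penicillium sp.4,Penicillium,Ascomycota,Eurotiomycetes,1
Mesembryanthemum forsskaollii,PAWD,flower,Aspergillus sp.7,Aspergillus,Ascomycota,Eurotiomycetes,1
Mesembryanthemum forsskaollii,PAWD,leaf,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,1
Mesembryanthemum forsskaollii,PAWD,stem,Curvularia sp.1,Curvularia,Ascomycota,Dothideomycetes,1
Mesembryanthemum forsskaollii,PAWD,flower,Phragmocamarosporium sp.2,Phragmocamarosporium,Ascomycota,Dothideomycetes,1
Mesembryanthemum forsskaollii,PAWD,leaf,Dark sterile mycelium sp.1,unclassified,unknown,unknown,1
Raphanus raphanistrum,NCAH,leaf,Aspergillus sp.8,Aspergillus,Ascomycota,Eurotiomycetes,1
Raphanus raphanistrum,NCAH,stem,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,1
Raphanus raphanistrum,NCAH,root,Curvularia sp.2,Curvularia,Ascomycota,Dothideomycetes,1
Raphanus raphanistrum,NCAH,leaf,Fusarium sp.2,Fusarium,Ascomycota,Sordariomycetes,1
Raphanus raphanistrum,NCAH,stem,Penicillium sp.5,Penicillium,Ascomycota,Eurotiomycetes,1
Raphanus raphanistrum,NCAH,root,Rhodotorula sp.,Rhodotorula,Basidiomycota,Microbotryomycetes,1
Suaeda vermiculata,PAWD,root,Curvularia sp.2,Curvularia,Ascomycota,Dothideomycetes,1
Suaeda vermiculata,PAWD,root,Diaporthe sp.,Diaporthe,Ascomycota,Sordariomycetes,1
Suaeda vermiculata,PAWD,root,Penicillium sp.6,Penicillium,Ascomycota,Eurotiomycetes,1
Suaeda vermiculata,PAWD,root,Ulocladium sp.1,Ulocladium,Ascomycota,Dothideomycetes,1
Suaeda vermiculata,PAWD,root,Ulocladium sp.2,Ulocladium,Ascomycota,Dothideomycetes,1
Suaeda vermiculata,PAWD,root,Dark sterile mycelium sp.2,unclassified,unknown,unknown,1
Zygophyllum coccineum,PAWD,leaf,Aspergillus sp.7,Aspergillus,Ascomycota,Eurotiomycetes,1
Zygophyllum coccineum,PAWD,stem,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,1
Zygophyllum coccineum,PAWD,leaf,Quambalaria sp.,Quambalaria,Basidiomycota,Exobasidiomycetes,1
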