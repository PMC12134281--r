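plant,location,tissue,morphospecies,genus,phylum,class_name,colony_count,matched_indices
Agathophora alopecuroides,PAWD,leaf,Aspergillus sp.1,Aspergillus,Ascomycota,Eurotiomycetes,2,camargo;berger_parker
Agathophora alopecuroides,PAWD,stem,Chaetomium sp.,Chaetomium,Ascomycota,Sordariomycetes,1,camargo;berger_parker
Agathophora alopecuroides,PAWD,root,Eurotium sp.,Eurotium,Ascomycota,Eurotiomycetes,1,camargo;berger_parker
Agathophora alopecuroides,PAWD,leaf,Trichosporon sp.,Trichosporon,Basidiomycota,Tremellomycetes,1,camargo;berger_parker
Anabasis setifera,PAWD,leaf,Aspergillus sp.2,Aspergillus,Ascomycota,Eurotiomycetes,4,shannon;simpson;camargo;berger_parker
Anabasis setifera,PAWD,stem,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,6,shannon;simpson;camargo;berger_parker
Anabasis setifera,PAWD,root,Aspergillus sp.4,Aspergillus,Ascomycota,Eurotiomycetes,2,shannon;simpson;camargo;berger_parker
Anabasis setifera,PAWD,leaf,Fusarium sp.1,Fusarium,Ascomycota,Sordariomycetes,1,shannon;simpson;camargo;berger_parker
Anabasis setifera,PAWD,stem,Penicillium sp.1,Penicillium,Ascomycota,Eurotiomycetes,1,shannon;simpson;camargo;berger_parker
Anabasis setifera,PAWD,root,Penicillium sp.2,Penicillium,Ascomycota,Eurotiomycetes,1,shannon;simpson;camargo;berger_parker
Anabasis setifera,PAWD,leaf,Phragmocamarosporium sp.1,Phragmocamarosporium,Ascomycota,Dothideomycetes,1,shannon;simpson;camargo;berger_parker
Anabasis setifera,PAWD,stem,Neocosmospora sp.,Neocosmospora,Ascomycota,Sordariomycetes,1,shannon;simpson;camargo;berger_parker
Halocnemum strobitaceum,PAWD,leaf,Aspergillus sp.5,Aspergillus,Ascomycota,Eurotiomycetes,2,shannon;simpson;camargo;berger_parker
Halocnemum strobitaceum,PAWD,stem,Aspergillus sp.6,Aspergillus,Ascomycota,Eurotiomycetes,2,shannon;simpson;camargo;berger_parker
Halocnemum strobitaceum,PAWD,leaf,Phaeocremonium sp.,Phaeocremonium,Ascomycota,Sordariomycetes,2,shannon;simpson;camargo;berger_parker
Halocnemum strobitaceum,PAWD,stem,Talaromyces sp.,Talaromyces,Ascomycota,Eurotiomycetes,2,shannon;simpson;camargo;berger_parker
Lantana camara L,NCAH,flower,Eurotium sp.,Eurotium,Ascomycota,Eurotiomycetes,2,simpson;camargo;berger_parker
Lantana camara L,NCAH,stem,Penicillium sp.3,Penicillium,Ascomycota,Eurotiomycetes,1,simpson;camargo;berger_parker
Lantana camara L,NCAH,flower,Penicillium sp.4,Penicillium,Ascomycota,Eurotiomycetes,1,simpson;camargo;berger_parker
Mesembryanthemum forsskaollii,PAWD,flower,Aspergillus sp.7,Aspergillus,Ascomycota,Eurotiomycetes,2,shannon
Mesembryanthemum forsskaollii,PAWD,leaf,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,3,shannon
Mesembryanthemum forsskaollii,PAWD,stem,Curvularia sp.1,Curvularia,Ascomycota,Dothideomycetes,2,shannon
Mesembryanthemum forsskaollii,PAWD,flower,Phragmocamarosporium sp.2,Phragmocamarosporium,Ascomycota,Dothideomycetes,2,shannon
Mesembryanthemum forsskaollii,PAWD,leaf,Dark sterile mycelium sp.1,unclassified,unknown,unknown,2,shannon
Raphanus raphanistrum,NCAH,leaf,Aspergillus sp.8,Aspergillus,Ascomycota,Eurotiomycetes,3,shannon;simpson;berger_parker
Raphanus raphanistrum,NCAH,stem,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,3,shannon;simpson;berger_parker
Raphanus raphanistrum,NCAH,root,Curvularia sp.2,Curvularia,Ascomycota,Dothideomycetes,3,shannon;simpson;berger_parker
Raphanus raphanistrum,NCAH,leaf,Fusarium sp.2,Fusarium,Ascomycota,Sordariomycetes,3,shannon;simpson;berger_parker
Raphanus raphanistrum,NCAH,stem,Penicillium sp.5,Penicillium,Ascomycota,Eurotiomycetes,2,shannon;simpson;berger_parker
Raphanus raphanistrum,NCAH,root,Rhodotorula sp.,Rhodotorula,Basidiomycota,Microbotryomycetes,1,shannon;simpson;berger_parker
Suaeda vermiculata,PAWD,root,Curvularia sp.2,Curvularia,Ascomycota,Dothideomycetes,2,shannon;berger_parker
Suaeda vermiculata,PAWD,root,Diaporthe sp.,Diaporthe,Ascomycota,Sordariomycetes,2,shannon;berger_parker
Suaeda vermiculata,PAWD,root,Penicillium sp.6,Penicillium,Ascomycota,Eurotiomycetes,2,shannon;berger_parker
Suaeda vermiculata,PAWD,root,Ulocladium sp.1,Ulocladium,Ascomycota,Dothideomycetes,1,shannon;berger_parker
Suaeda vermiculata,PAWD,root,Ulocladium sp.2,Ulocladium,Ascomycota,Dothideomycetes,1,shannon;berger_parker
Suaeda vermiculata,PAWD,root,Dark sterile mycelium sp.2,unclassified,unknown,unknown,1,shannon;berger_parker
Zygophyllum coccineum,PAWD,leaf,Aspergillus sp.7,Aspergillus,Ascomycota,Eurotiomycetes,1,shannon;simpson;camargo;berger_parker
Zygophyllum coccineum,PAWD,stem,Aspergillus sp.3,Aspergillus,Ascomycota,Eurotiomycetes,1,shannon;simpson;camargo;berger_parker
Zygophyllum coccineum,PAWD,leaf,Quambalaria sp.,Quambalaria,Basidiomycota,Exobasidiomycetes,1,shannon;simpson;camargo;berger_parker
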