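otu,taxon,phylum,closest_match,accession
OTU1,Brachyura,Crustacea,Pirimela denticulata,FR851241
OTU2,Brachyura,Crustacea,Polybius henslowii,LN614707
OTU3,Brachyura,Crustacea,Goneplax rhomboides,LN614708
OTU4,Anomura,Crustacea,Pisidia longicornis,FR851242
OTU5,Euphausiacea,Crustacea,Nyctiphanes couchii,FR851243
OTU6,Gebiidea,Crustacea,Jaxea nocturna,FR851244
OTU7,Axiidea,Crustacea,Callianassa subterranea,FR851245
OTU8,Axiidea,Crustacea,Callianassa sp.,FR851246
OTU9,Axiidea,Crustacea,Callianassidae,FR851247
OTU10,Gebiidea,Crustacea,Upogebiidae,FR851248
OTU11,Caridea,Crustacea,Alpheus glaber,FR851249
OTU12,Caridea,Crustacea,Alpheidae,FR851250
OTU13,Copepoda,Crustacea,Metridia lucens,LN614709
OTU14,Bivalvia,Mollusca,Limnoperna securis,FR851251
OTU15,Bivalvia,Mollusca,Mytilidae,FR851252
OTU16,Teleostei,Chordata,Gobiinae,FR851253
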