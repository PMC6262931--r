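copepod_id,species,condition,size_class
C1,Diaixis pygmaea,downwelling,small
C2,Clausocalanus sp.,downwelling,small
C3,Temora longicornis,downwelling,small
C4,Acartia clausii,downwelling,small
C5,Isias clavipes,downwelling,small
C6,Centropages chierchiae,downwelling,small
C7,Paraeuchaeta hebes,downwelling,large
C8,Oithona sp.,upwelling,small
C9,Corycaeus sp.,upwelling,small
C10,Paracalanus parvus,upwelling,small
C11,Pseudocalanus elongatus,upwelling,small
C12,Ctenocalanus vanus,upwelling,small
C13,Aetideus armatus,upwelling,small
C14,Centropages typicus,upwelling,small
C15,Pleuromamma gracilis,upwelling,small
C16,Calanoides carinatus,upwelling,large
C17,Calanus helgolandicus,upwelling,large
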