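copepod_id,OTU1,OTU2,OTU3,OTU4,OTU5,OTU6,OTU7,OTU8,OTU9,OTU10,OTU11,OTU12,OTU13,OTU14,OTU15,OTU16
C1,0,0,0,3,0,0,0,0,0,0,0,0,1,0,0,0
C2,3,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0
C3,2,0,0,2,0,0,0,0,0,0,0,0,0,0,0,0
C4,4,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
C5,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,4
C6,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
C7,4,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
C8,4,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
C9,0,0,0,0,0,0,0,0,0,0,0,4,0,0,0,0
C10,3,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
C11,4,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
C12,1,0,0,0,0,0,1,1,1,0,0,0,0,0,0,0
C13,2,1,2,0,0,0,0,0,0,0,0,0,0,0,0,0
C14,1,0,0,0,0,0,0,0,0,0,0,0,0,2,1,0
C15,5,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
C16,2,0,0,0,0,2,0,0,0,1,0,0,0,0,0,0
C17,2,0,0,2,0,0,0,0,0,0,0,0,0,0,0,0
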