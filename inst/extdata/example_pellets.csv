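location_id,habitat,transect_id,transect_presence
L1,forest,A,1
L1,forest,D,0
L1,forest,M,1
L1,forest,P,0
L2,nonforest,A,0
L2,nonforest,D,0
L2,nonforest,M,0
L2,nonforest,P,0
L3,forest,A,1
L3,forest,D,1
L3,forest,M,0
L3,forest,P,1
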