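location_id,habitat,line_id,night,traps_set,possum_captures,nontarget_captures,sprung_empty
L1,forest,AA,1,10,1,0,0
L1,forest,AA,2,10,0,1,0
L1,forest,DD,1,10,0,0,0
L1,forest,DD,2,10,2,0,1
L1,forest,MM,1,10,0,0,0
L1,forest,MM,2,10,0,0,0
L1,forest,PP,1,10,1,0,0
L1,forest,PP,2,10,0,0,0
L2,nonforest,AA,1,10,0,0,0
L2,nonforest,AA,2,10,0,0,0
L2,nonforest,DD,1,10,0,1,0
L2,nonforest,DD,2,10,0,0,0
L2,nonforest,MM,1,10,0,0,0
L2,nonforest,MM,2,10,0,0,0
L3,forest,AA,1,10,0,0,0
L3,forest,AA,2,10,0,0,1
L3,forest,DD,1,10,0,0,0
L3,forest,DD,2,10,0,0,0
L3,forest,MM,1,10,1,0,0
L3,forest,MM,2,10,1,0,0
L3,forest,PP,1,10,0,0,0
L3,forest,PP,2,10,0,0,0
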