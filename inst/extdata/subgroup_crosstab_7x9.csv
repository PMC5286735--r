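subgroup,TS1,TS2,TS3,TS4,TS5,TS6,TS7,TS8,TS9
SS1,26,79,27,36,0,14,3,6,1
SS2,0,69,4,2,0,31,29,19,0
SS3,113,3,13,4,2,0,0,1,0
SS4,17,3,30,28,33,1,12,8,0
SS5,4,4,44,14,12,20,29,2,1
SS6,56,0,6,5,22,0,0,0,20
SS7,3,3,3,24,2,3,1,9,27
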