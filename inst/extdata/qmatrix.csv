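"item","A1","A2"
"Item1",1,0
"Item2",1,0
"Item3",1,0
"Item4",1,0
"Item5",0,1
"Item6",0,1
"Item7",0,1
"Item8",0,1
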