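"","A2","A3","B2","B3","B4","B5","B6","B7","B8","B9","B10","B11","Y"
"A2",0,0,0,0,0.1117,0,0,0,0,0,0,0,0
"A3",0.1028,0,0,0,0,0,0,0,0,0,0,0,0
"B2",0,0,0,1,0,0.125,0,0,0,0,0,0,0
"B3",0,0,1,0,0,0,0,0,0,0,0,0,0
"B4",0,0,0,0,0,0,0,0,0,0,0,0,0.1371
"B5",0,0,0,0,0.1117,0,0,0,0,0,0,0,0
"B6",0,0,0,0.0987,0,0,0,0,0,0,0,0,0
"B7",0,0,0,0,0,0.1386,0,0,1,1,0,0,0
"B8",0,0,0,0,0,0,0,1,0,1,0,0,0
"B9",0,0,0,0,0,0,0,1,1,0,0,0,0
"B10",0,0,0.1006,0,0,0,0,0.0962,0,0,0,0,0
"B11",0,0,0,0,0,0.1134,0,0,0,0,0,0,0
"Y",0,0,0,0,0,0,0,0,0,0,0,0,0
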