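"","D","C","M","Rc"
"A2",0.653,0.571,1.224,0.083
"A3",0.624,0.397,1.021,0.228
"B2",0.811,0.65,1.461,0.16
"B3",0.759,0.707,1.466,0.052
"B4",0.566,0.807,1.373,-0.242
"B5",0.663,1.202,1.865,-0.539
"B6",0.701,0.57,1.271,0.131
"B7",0.786,0.596,1.382,0.189
"B8",0.769,0.585,1.354,0.184
"B9",0.74,0.577,1.317,0.163
"B10",0.949,0.302,1.252,0.647
"B11",0.659,0.441,1.1,0.219
"Y",0.336,1.611,1.947,-1.275
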