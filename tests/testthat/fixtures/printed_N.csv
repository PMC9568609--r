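"","A2","A3","B2","B3","B4","B5","B6","B7","B8","B9","B10","B11","Y"
"A2",0,0.072,0.016,0.019,0.088,0.038,0.02,0.013,0.012,0.012,0.012,0.017,0.091
"A3",0.087,0,0.018,0.019,0.091,0.034,0.019,0.013,0.012,0.012,0.012,0.016,0.049
"B2",0.016,0.014,0,0.11,0.025,0.085,0.063,0.019,0.018,0.019,0.019,0.015,0.088
"B3",0.016,0.014,0.09,0,0.019,0.089,0.067,0.016,0.017,0.017,0.013,0.017,0.084
"B4",0.046,0.014,0.024,0.025,0,0.024,0.021,0.015,0.015,0.015,0.015,0.037,0.101
"B5",0.046,0.013,0.021,0.02,0.091,0,0.026,0.017,0.013,0.013,0.013,0.039,0.104
"B6",0.023,0.02,0.045,0.077,0.032,0.066,0,0.013,0.014,0.014,0.014,0.029,0.079
"B7",0.013,0.013,0.02,0.017,0.019,0.101,0.023,0,0.076,0.078,0.018,0.015,0.081
"B8",0.012,0.015,0.019,0.02,0.023,0.087,0.024,0.083,0,0.075,0.019,0.017,0.067
"B9",0.012,0.016,0.021,0.02,0.023,0.069,0.021,0.082,0.077,0,0.014,0.018,0.07
"B10",0.012,0.016,0.077,0.02,0.023,0.067,0.023,0.068,0.082,0.078,0,0.025,0.075
"B11",0.021,0.02,0.019,0.054,0.024,0.084,0.023,0.016,0.02,0.016,0.016,0,0.091
"Y",0.027,0.012,0.023,0.024,0.019,0.016,0.011,0.016,0.013,0.013,0.012,0.011,0
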