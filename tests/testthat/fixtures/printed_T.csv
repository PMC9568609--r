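"","A2","A3","B2","B3","B4","B5","B6","B7","B8","B9","B10","B11","Y"
"A2",0.023,0.081,0.034,0.039,0.112,0.065,0.036,0.027,0.025,0.025,0.021,0.031,0.135
"A3",0.103,0.015,0.035,0.038,0.115,0.062,0.034,0.026,0.025,0.025,0.02,0.03,0.096
"B2",0.038,0.028,0.029,0.132,0.055,0.125,0.085,0.038,0.036,0.037,0.03,0.032,0.145
"B3",0.037,0.027,0.109,0.031,0.049,0.125,0.086,0.033,0.034,0.033,0.024,0.033,0.138
"B4",0.06,0.025,0.04,0.043,0.021,0.052,0.035,0.028,0.028,0.028,0.023,0.047,0.137
"B5",0.064,0.026,0.04,0.041,0.112,0.031,0.041,0.032,0.027,0.027,0.022,0.052,0.149
"B6",0.042,0.032,0.067,0.099,0.058,0.1,0.021,0.029,0.029,0.029,0.024,0.043,0.129
"B7",0.033,0.026,0.041,0.04,0.049,0.139,0.041,0.026,0.096,0.098,0.029,0.032,0.135
"B8",0.032,0.028,0.04,0.043,0.051,0.126,0.042,0.103,0.025,0.095,0.03,0.033,0.121
"B9",0.031,0.028,0.041,0.042,0.049,0.108,0.04,0.101,0.096,0.024,0.025,0.033,0.122
"B10",0.035,0.031,0.101,0.052,0.055,0.12,0.048,0.096,0.107,0.104,0.014,0.043,0.142
"B11",0.04,0.032,0.04,0.072,0.05,0.113,0.04,0.032,0.035,0.031,0.025,0.014,0.136
"Y",0.035,0.019,0.033,0.035,0.032,0.035,0.02,0.025,0.022,0.021,0.017,0.018,0.026
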