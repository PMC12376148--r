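enzyme,treatment,mean,se
SOD,Mohajer,0.006,0.001
SOD,Dashtestan,0.006,0.001
SOD,Barekat,0.007,0.001
SOD,Chamran,0.025,0.001
SOD,Shevin,0.007,0.001
SOD,Sistan,0.007,0.001
SOD,Hamidieh,0.007,0.001
SOD,Behbahan,0.013,0.001
SOD,Dezful,0.015,0.002
SOD,Jiroft,0.015,0.002
POD,Mohajer,0.018,0.002
POD,Dashtestan,0.025,0.002
POD,Barekat,0.018,0.001
POD,Chamran,0.115,0.001
POD,Shevin,0.053,0.001
POD,Sistan,0.022,0.001
POD,Hamidieh,0.038,0.002
POD,Behbahan,0.036,0.002
POD,Dezful,0.046,0.002
POD,Jiroft,0.065,0.002
CAT,Mohajer,0.075,0.003
CAT,Dashtestan,0.055,0.003
CAT,Barekat,0.072,0.001
CAT,Chamran,0.165,0.003
CAT,Shevin,0.163,0.015
CAT,Sistan,0.095,0.003
CAT,Hamidieh,0.130,0.120
CAT,Behbahan,0.125,0.003
CAT,Dezful,0.198,0.001
CAT,Jiroft,0.550,0.017
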