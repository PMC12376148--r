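treatment,GRR,R0,r,lambda,T,r_4dp
Mohajer,369.4,220.7,0.115,1.122,40.7,
Dashtestan,604.2,96.0,0.093,1.098,42.7,
Barekat,315.4,250.2,0.119,1.127,41.6,0.1194
Chamran,328.4,78.2,0.100,1.105,46.3,
Shevin,179.1,64.5,0.088,1.092,43.1,
Sistan,172.2,80.8,0.101,1.106,43.0,
Hamidieh,127.4,73.9,0.101,1.106,42.3,
Behbahan,111.7,50.6,0.095,1.100,46.5,
Dezful,121.8,53.7,0.094,1.098,48.4,
Jiroft,196.4,31.3,0.078,1.082,46.1,0.0786
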