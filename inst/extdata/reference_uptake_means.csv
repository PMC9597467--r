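genotype,treatment,nutrient,uptake_g
TDr1499,non-F,N,2.6
TDr1499,+F,N,4.7
TDr1649,non-F,N,2.2
TDr1649,+F,N,3.7
TDr1899,non-F,N,1.5
TDr1899,+F,N,2.3
TDr2029,non-F,N,2.1
TDr2029,+F,N,2.9
TDr2484,non-F,N,1.9
TDr2484,+F,N,2.6
TDr2948,non-F,N,2.9
TDr2948,+F,N,3.5
TDr1499,non-F,P,0.3
TDr1499,+F,P,0.8
TDr1649,non-F,P,0.3
TDr1649,+F,P,0.6
TDr1899,non-F,P,0.2
TDr1899,+F,P,0.3
TDr2029,non-F,P,0.3
TDr2029,+F,P,0.4
TDr2484,non-F,P,0.2
TDr2484,+F,P,0.4
TDr2948,non-F,P,0.3
TDr2948,+F,P,0.6
TDr1499,non-F,K,2.2
TDr1499,+F,K,3.9
TDr1649,non-F,K,2.0
TDr1649,+F,K,2.8
TDr1899,non-F,K,1.4
TDr1899,+F,K,1.9
TDr2029,non-F,K,1.7
TDr2029,+F,K,2.1
TDr2484,non-F,K,1.7
TDr2484,+F,K,2.1
TDr2948,non-F,K,2.1
TDr2948,+F,K,2.9
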