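,Dendrophysa russelli,Johnius belangerii,Johnius carouna,Otolithes ruber,Panna microdon,Nemapteryx caelatus,Arius maculatus,Cryptarius truncatus,Hexanematichtys sagor,Osteogeneiosus militaris,Plicofollis argyropleuron,Coilia dussumieri,Setipinna taty,Thryssa hamiltonii
Dendrophysa russelli,8,0,0,2,0,0,0,0,0,0,0,0,0,0
Johnius belangerii,0,10,0,0,0,0,0,0,0,0,0,0,0,0
Johnius carouna,0,0,10,0,0,0,0,0,0,0,0,0,0,0
Otolithes ruber,1,0,0,9,0,0,0,0,0,0,0,0,0,0
Panna microdon,0,0,0,0,10,0,0,0,0,0,0,0,0,0
Nemapteryx caelatus,0,0,0,0,0,7,0,2,0,0,1,0,0,0
Arius maculatus,0,0,0,0,0,0,10,0,0,0,0,0,0,0
Cryptarius truncatus,0,0,0,0,0,3,0,7,0,0,0,0,0,0
Hexanematichtys sagor,0,0,0,0,0,0,0,0,10,0,0,0,0,0
Osteogeneiosus militaris,0,0,0,0,0,0,0,1,0,9,0,0,0,0
Plicofollis argyropleuron,0,0,0,0,0,0,0,0,0,0,10,0,0,0
Coilia dussumieri,0,0,0,0,0,0,0,0,0,0,0,10,0,0
Setipinna taty,0,0,0,0,0,0,0,0,0,0,0,0,9,1
Thryssa hamiltonii,0,0,0,0,0,0,0,0,0,0,0,0,0,10
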