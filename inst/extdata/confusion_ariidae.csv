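,Nemapteryx caelatus,Arius maculatus,Cryptarius truncatus,Hexanematichtys sagor,Osteogeneiosus militaris,Plicofollis argyropleuron
Nemapteryx caelatus,8,0,2,0,0,0
Arius maculatus,0,10,0,0,0,0
Cryptarius truncatus,1,0,9,0,0,0
Hexanematichtys sagor,0,0,0,10,0,0
Osteogeneiosus militaris,1,0,0,0,9,0
Plicofollis argyropleuron,0,0,0,0,0,10
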