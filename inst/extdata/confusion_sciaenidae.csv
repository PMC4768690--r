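,Dendrophysa russelli,Johnius belangerii,Johnius carouna,Otolithes ruber,Panna microdon
Dendrophysa russelli,9,0,0,1,0
Johnius belangerii,0,10,0,0,0
Johnius carouna,0,0,10,0,0
Otolithes ruber,1,0,0,9,0
Panna microdon,0,0,0,0,10
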