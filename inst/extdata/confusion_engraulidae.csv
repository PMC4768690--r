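,Coilia dussumieri,Setipinna taty,Thryssa hamiltonii
Coilia dussumieri,10,0,0
Setipinna taty,0,10,0
Thryssa hamiltonii,0,1,9
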