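set,metal,value
ASV,As,13
ASV,Pb,20
ASV,Zn,95
ASV,Fe,47200
ASV,Cd,0.3
ASV,Cu,45
ASV,Cr,90
ASV,Ni,68
UCC,As,4.8
UCC,Pb,17
UCC,Zn,67
UCC,Fe,39200
UCC,Cd,0.09
UCC,Cu,28
UCC,Cr,92
UCC,Ni,47
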