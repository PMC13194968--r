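receptor,ing_r,inh_r,ef_d,ed,bw,sa,af,pef,at_ca
child,200,7.6,350,6,15,2800,0.2,1.36e9,25550
adult,100,20,350,24,70,5700,0.07,1.36e9,25550
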