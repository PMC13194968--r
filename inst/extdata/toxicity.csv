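metal,rfd_ing,rfd_inh,rfd_derm,csf_ing,csf_inh,csf_derm,abs,provenance
As,3.0e-4,3.01e-4,1.23e-4,1.5,15.1,3.66,0.03,IRIS oral RfD/CSF; inhalation and dermal per RSL unit-risk and GIABS conventions
Pb,3.5e-3,3.52e-3,5.25e-4,8.5e-3,4.2e-2,NA,0.001,provisional oral RfD (WHO/IEUBK practice); CalEPA slope factors; dermal = oral x GIABS 0.15 convention
Cd,1.0e-3,1.0e-3,1.0e-5,6.1,6.3,NA,0.001,IRIS dietary RfD; inhalation unit-risk conversion; dermal = oral x GIABS 0.01 convention
Cr,3.0e-3,2.86e-5,6.0e-5,0.5,42,20,0.001,Cr(VI) IRIS oral RfD; RSL inhalation RfC conversion; dermal = oral x GIABS 0.02 convention
Ni,2.0e-2,2.06e-2,5.4e-3,NA,0.84,NA,0.001,IRIS soluble-salt oral RfD; refractory-dust inhalation slope; dermal = oral x GIABS 0.27
Cu,4.0e-2,4.02e-2,1.2e-2,NA,NA,NA,0.001,HEAST oral RfD; no accepted slope factor (non-carcinogenic only)
Zn,3.0e-1,3.0e-1,6.0e-2,NA,NA,NA,0.001,IRIS oral RfD; no accepted slope factor (non-carcinogenic only)
Fe,7.0e-1,7.0e-1,1.4e-1,NA,NA,NA,0.001,PPRTV provisional oral RfD; no accepted slope factor (non-carcinogenic only)
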