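index,lower,upper,label
igeo,-Inf,0,unpolluted
igeo,0,1,unpolluted to moderately polluted
igeo,1,2,moderately polluted
igeo,2,3,moderately to strongly polluted
igeo,3,4,strongly polluted
igeo,4,5,strongly to extremely polluted
igeo,5,Inf,extremely polluted
ef,0,2,deficiency to minimal enrichment
ef,2,5,moderate enrichment
ef,5,20,significant enrichment
ef,20,40,very high enrichment
ef,40,Inf,extremely high enrichment
cf,0,1,low contamination
cf,1,3,moderate contamination
cf,3,6,considerable contamination
cf,6,Inf,very high contamination
pli,0,1,unpolluted
pli,1,2,moderately polluted
pli,2,3,highly polluted
pli,3,Inf,extremely polluted
hq,0,1,no significant non-carcinogenic risk
hq,1,Inf,adverse non-carcinogenic risk
tcr,0,1e-6,insignificant risk
tcr,1e-6,1e-4,tolerable risk
tcr,1e-4,Inf,unacceptable carcinogenic risk
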