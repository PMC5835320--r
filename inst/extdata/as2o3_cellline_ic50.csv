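cellline,ic50_uM,sd_uM,pair,role
CCRF-CEM,0.48,0.22,leukemia,parental
CEM/ADR5000,0.90,0.38,leukemia,resistant
U87.MG,47.82,1.25,glioblastoma,parental
U87.MG dEGFR,15.60,0.93,glioblastoma,resistant
HCT116 p53+/+,12.68,0.74,colon,parental
HCT116 p53-/-,90.83,0.83,colon,resistant
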