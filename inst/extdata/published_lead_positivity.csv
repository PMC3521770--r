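antigen,overall_cancer_pct,overall_control_pct,additive_cancer_pct,additive_control_pct,confirmed
alpha enolase BirA,15,2,12,2,TRUE
EGFR2 C-BirA,1,0,1,0,FALSE
p53 C-BirA,14,2,9,2,TRUE
p53-EP C-BirA,7,0,5,0,FALSE
cytokeratin 20 BirA,10,2,8,2,TRUE
cytokeratin 8 BirA,4,0,3,0,TRUE
NY-ESO-1 C-BirA,10,2,6,2,FALSE
Lmyc2,10,2,9,2,TRUE
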