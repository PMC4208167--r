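condition,beta,sd,sn_db
baseline,1.0037,0.0063,43.48
optimal,1.0004,0.0035,50.5
optimal_refined,NA,NA,53.38
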