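motif,S,pair,param_1,param_2,dir_1,dir_2,degree_nb,class_nb,degree_add,degree_add_max,degree_add_min,class_add,flag
canonical_m,1,K_T/k_dA,K_T,k_dA,1,-1,109.50434,strong,102.77089,102.77089,0,synergistic,
canonical_m,1,k_ST/k_dA,k_ST,k_dA,1,-1,178.58382,strong,164.33111,164.33111,0,synergistic,
canonical_m,1,k_dA/k_dB,k_dA,k_dB,-1,-1,1119.1483,strong,1045.3422,1045.3422,0,synergistic,
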