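sample,two_A_par_G,two_A_perp_G,S_ref,tau_c_ns_ref
control,50.116,18.576,0.606,2.89
DDA,49.070,18.977,0.578,1.12
DDA+MCE,50.892,18.414,0.624,2.15
DDA+MCI,50.739,18.549,0.618,2.07
DDA+QUE,50.758,18.416,0.621,2.25
DDA+LUT,51.019,18.267,0.629,3.28
DDA+API,51.158,18.411,0.629,2.23
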