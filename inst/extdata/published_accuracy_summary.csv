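trait,PBLUP,GBLUP,BayesB,BayesC,BRR,BL,RKHS,mean_printed,hc2
AWT,0.549,0.606,0.610,0.603,0.601,0.594,0.636,0.608,0.655
EMY,0.415,0.557,0.629,0.608,0.608,0.580,0.621,0.600,0.262
SSC,0.630,0.708,0.726,0.723,0.719,0.726,0.748,0.725,0.364
TC,0.159,0.365,0.400,0.402,0.401,0.385,0.363,0.386,0.767
TMY,0.507,0.652,0.753,0.718,0.433,0.638,0.710,0.630,0.220
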