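energy_kev,material,mu_over_rho_cm2_g
100,lead,5.549
140,lead,2.420
150,lead,2.014
159,lead,1.760
200,lead,0.9985
250,lead,0.5876
300,lead,0.4031
400,lead,0.2323
440,lead,0.1990
500,lead,0.1614
529,lead,0.1491
600,lead,0.1248
100,nai,1.669
140,nai,0.700
150,nai,0.590
159,nai,0.520
200,nai,0.305
250,nai,0.205
300,nai,0.155
400,nai,0.115
440,nai,0.107
500,nai,0.0955
529,nai,0.0905
600,nai,0.0830
100,pmma,0.1641
140,pmma,0.1494
150,pmma,0.1456
159,pmma,0.1425
200,pmma,0.1328
250,pmma,0.1226
300,pmma,0.1152
400,pmma,0.1031
440,pmma,0.0990
500,pmma,0.0941
529,pmma,0.0917
600,pmma,0.0870
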