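camera,crystal_in,crystal_mm,intrinsic_res_mm,energy_res_pct,le_label,le_d_mm,le_t_mm,le_L_mm,me_label,me_d_mm,me_t_mm,me_L_mm
GE Infinia,3/8,9.5,3.8,9.8,LEHR,1.50,0.20,35.00,MEGP,3.00,1.05,58.00
Millennium MG,3/8,9.5,3.7,9.7,LEHR,1.80,0.18,41.00,MEGP,3.00,1.20,42.00
GE NMCT,3/8,9.5,3.7,9.5,LEHR,1.50,0.20,35.00,MEGP,3.00,1.05,58.00
GE NMCT,5/8,15.9,4.5,9.5,LEHR,1.50,0.20,35.00,MEGP,3.00,1.05,58.00
Philips Brightview,3/8,9.5,3.3,9.6,CHR,2.03,0.152,48.00,MEGP,3.40,0.86,58.40
Siemens E.CAM,3/8,9.5,3.8,9.9,LEHR,1.11,0.16,24.05,MELP,2.94,1.14,40.64
Siemens E.CAM,5/8,15.9,4.5,9.9,LEHR,1.11,0.16,24.05,MELP,2.94,1.14,40.64
Picker AXIS/IRIX,3/8,9.5,3.3,9.5,LEHR,1.22,0.20,27.00,MEGP,3.40,0.86,58.40
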