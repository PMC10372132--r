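camera,collimator,class,hole_diameter_mm,septum_mm,length_mm
GE Infinia,LEHR,LE,1.50,0.20,35.00
GE Infinia,ELEGP,LE,2.50,0.40,40.00
GE Infinia,MEGP,ME,3.00,1.05,58.00
Millennium VG,LEHR,LE,1.50,0.20,35.00
Millennium VG,LEGP,LE,1.90,0.20,35.00
Millennium VG,MEGP,ME,3.00,1.05,58.00
Millennium MG,LEHR,LE,1.80,0.18,41.00
Millennium MG,LEGP,LE,2.50,0.25,43.00
Millennium MG,MEGP,ME,3.00,1.20,42.00
Philips Brightview,CHR,LE,2.03,0.152,48.00
Philips Brightview,MEGP,ME,3.40,0.86,58.40
Siemens E.CAM,LEHR,LE,1.11,0.16,24.05
Siemens E.CAM,MELP,ME,2.94,1.14,40.64
Siemens Symbia,LEHR,LE,1.11,0.16,24.05
Siemens Symbia,MELP,ME,2.94,1.14,40.64
Picker AXIS/IRIX,LEHR,LE,1.22,0.20,27.00
Picker AXIS/IRIX,LEGP,LE,1.40,0.25,25.40
Picker AXIS/IRIX,MEGP,ME,3.40,0.86,58.40
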