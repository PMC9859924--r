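trait,qtl_name,linkage_group,position_cM,effect_size,population,reference
DF,DF414,1,67.11,0.68,DOR 364 x BAT 477,Diaz et al.
DF,DF51,5,45.21,0.45,DOR 364 x BAT 477,Diaz et al.
DF,DF52,5,56.71,0.49,DOR 364 x BAT 477,Diaz et al.
DF,DF53,5,82.21,0.46,DOR 364 x BAT 477,Diaz et al.
DF,DF54,5,105.21,0.43,DOR 364 x BAT 477,Diaz et al.
DF,DF11a,11,96.51,-0.6,DOR 364 x BAT 477,Diaz et al.
DF,DF11b,11,108.71,-0.49,DOR 364 x BAT 477,Diaz et al.
DF,EM86,2,21.6,0.57,Bunsi x Newport,Ender and Kelly
DF,EM78,7,1.1,-0.6,Bunsi x Newport,Ender and Kelly
DF,EM550,7,13.6,-0.96,Bunsi x Newport,Ender and Kelly
DF,EM223,7,8.6,-1.21,Bunsi x Newport,Ender and Kelly
DF,DF121,1,51,0.02,SER48 x Merlot,Hoyos-Villegas et al.
DF,DF122,1,62,-0.69,SER48 x Merlot,Hoyos-Villegas et al.
DF,DF111,1,47,-0.62,SER48 x Merlot,Hoyos-Villegas et al.
DF,DF131,1,9,0.12,SER48 x Merlot,Hoyos-Villegas et al.
DF,DF112,1,40,0.03,SER48 x Merlot,Hoyos-Villegas et al.
DF,DF123,1,59,-0.66,SER48 x Merlot,Hoyos-Villegas et al.
DF,DFmn1,1,16.9,-0.8,AN-37 x P02630,Hoyos-Villegas et al.
DF,DFmn2,1,105.7,-0.8,AN-37 x P02630,Hoyos-Villegas et al.
WM,WM2010,3,91.5,-7.2,AN-37 x P02630,Hoyos-Villegas et al.
WM,WM31,3,111.1,-4,AN-37 x P02630,Hoyos-Villegas et al.
WM,DSI1,2,8,3.15,Bunsi x Newport,Ender and Kelly
WM,DSI2,2,21,-2.66,Bunsi x Newport,Ender and Kelly
WM,DSI3,5,27.7,3.16,Bunsi x Newport,Ender and Kelly
WM,DSI4,7,8.6,-4.17,Bunsi x Newport,Ender and Kelly
WM,DSI5,7,14.8,-4.01,Bunsi x Newport,Ender and Kelly
WM,DSI6,8,1.4,2.93,Bunsi x Newport,Ender and Kelly
SY,Yd21,2,151.2,-46.88,DOR 364 x BAT 477,Diaz et al.
SY,Yd71,7,35.1,-36.91,DOR 364 x BAT 477,Diaz et al.
SY,Yd72,7,47.8,-97.3,DOR 364 x BAT 477,Diaz et al.
SY,syMO14,3,113.7,-153.6,BK004-001 x H68-4,Sandhu et al.
SY,syMO16a,7,10.6,-170.9,BK004-001 x H68-4,Sandhu et al.
SY,syMO16b,8,0.5,-140.2,BK004-001 x H68-4,Sandhu et al.
SY,SY10v1,10,41,-178.77,SER48 x Merlot,Hoyos-Villegas et al.
SY,SY3v3,3,53,-155.91,SER48 x Merlot,Hoyos-Villegas et al.
SY,SY7v3,7,51,-197.46,SER48 x Merlot,Hoyos-Villegas et al.
SY,SY7v4a,7,68,-178.85,SER48 x Merlot,Hoyos-Villegas et al.
SY,SY7v4b,7,67,-97.54,SER48 x Merlot,Hoyos-Villegas et al.
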