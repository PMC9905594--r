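species,strain,growth_note,fungal_m1,fungal_m1_se,fungal_m1_sig,bacterial_m1,bacterial_m1_se,bacterial_m1_sig,adj_r2_m1,bacterial_m2,bacterial_m2_se,bacterial_m2_sig,adj_r2_m2,n_vocs_m2,fungal_m3,fungal_m3_se,fungal_m3_sig,adj_r2_m3,n_vocs_m3
L. exigua,HFSF103,8.1 > 7.3*,1.8,0.16,**,0.20,0.023,**,0.739,0.29,0.029,**,0.797,27,1.4,0.30,**,0.205,34
L. exigua,HFSF26,ns,0.7,0.20,**,0.29,0.019,**,0.723,0.23,0.039,**,0.539,30,1.01,0.052,**,0.292,33
L. exigua,Ks2_4,8.9 < 9.8*,0.3,0.17,ns,0.29,0.023,**,0.699,0.14,0.028,**,0.472,28,0.8,0.28,*,0.287,39
L. exigua,Pats4_2,ns,1.1,0.18,**,0.27,0.024,**,0.757,0.33,0.011,**,0.981,18,0.9,0.11,**,0.271,55
L. exigua,Pr2s22,ns,0.66,0.077,**,0.059,0.0086,**,0.633,0.08,0.019,**,0.365,31,0.55,0.06,**,0.06,37
L. gamsii,Ks2_13,7.7 < 8.0*,0.25,0.094,*,0.20,0.014,**,0.75,0.11,0.023,**,0.447,25,0.50,0.030,**,0.204,30
L. gamsii,M10,ns,0.19,0.108,ns,0.20,0.014,**,0.71,0.16,0.023,**,0.647,29,0.51,0.039,**,0.202,27
L. gamsii,M42,ns,0.02,0.133,ns,0.27,0.015,**,0.769,0.27,0.024,**,0.833,26,-0.03,0.087,ns,0.273,29
L. gamsii,Pats3_1,7.9 < 9.0*,0.3,0.16,*,0.22,0.018,**,0.664,0.28,0.047,**,0.524,31,-0.17,0.134,ns,0.219,26
L. gamsii,Pr2s1,ns,0.34,0.066,**,0.18,0.016,**,0.688,0.14,0.031,**,0.45,26,0.21,0.017,**,0.179,35
L. hyalina,Ks1_7,8.6 > 8.4*,0.45,0.098,**,0.18,0.015,**,0.679,0.37,0.043,**,0.692,33,0.09,0.086,ns,0.182,31
L. hyalina,Ks2_11,ns,0.59,0.086,**,0.17,0.014,**,0.699,0.21,0.033,**,0.561,32,0.63,0.068,**,0.173,29
L. hyalina,Ks2_12,ns,0.6,0.11,**,0.24,0.015,**,0.762,0.29,0.047,**,0.52,35,0.36,0.041,**,0.237,28
L. hyalina,Patw2_7,6.3 < 8.5*,0.14,0.035,**,0.22,0.012,**,0.781,0.13,0.019,**,0.63,30,0.3,0.11,*,0.224,29
L. sclerotiella,HFSF81,7.7 > 7.2*,0.89,0.036,**,0.01,0.036,ns,0.877,-0.01,0.011,ns,-0.054,10,0.91,0.020,**,0.012,80
L. sclerotiella,HFSF83,7.4 < 8.5*,0.2,0.14,ns,0.31,0.019,**,0.771,0.4,0.059,**,0.639,26,-0.13,0.097,ns,0.312,40
L. sclerotiella,HFSF85,8.3 > 7.5*,0.5,0.13,**,0.27,0.019,**,0.751,0.2,0.058,**,0.457,25,0.46,0.048,**,0.272,41
L. solitaria,OAS3,ns,0.96,0.037,**,0.022,0.0042,**,0.911,0.03,0.021,ns,0.045,29,0.86,0.030,**,0.022,38
L. solitaria,OAS4,ns,0.93,0.076,**,0.040,0.0089,**,0.727,0.08,0.028,*,0.217,30,0.11,0.060,ns,0.038,37
L. solitaria,OAS5,ns,0.4,0.22,**,0.22,0.022,**,0.583,0.23,0.055,**,0.33,35,0.2,0.11,ns,0.218,28
E. galaxiae,M1,7.4 > 6.9*,-0.2,0.29,ns,0.55,0.035,**,0.718,0.59,0.082,**,0.668,26,-0.17,0.138,ns,0.552,29
E. galaxiae,M22,ns,-0.1,0.22,ns,0.60,0.025,**,0.855,0.56,0.042,**,0.885,24,-0.9,0.11,**,0.598,30
E. galaxiae,Pfs28,6.6 < 6.8*,1.00,0.024,**,0.01,0.003,ns,0.95,-0.01,0.002,**,0.388,33,1.18,0.035,**,0.007,29
E. galaxiae,Pr1s18,6.9 < 7.3*,0.6,0.30,ns,0.57,0.035,**,0.787,0.53,0.092,**,0.539,29,0.6,0.16,**,0.572,40
E. galaxiae,Prw1_1,8.9 > 8.4*,-0.01,0.186,ns,0.61,0.029,**,0.833,0.63,0.073,**,0.718,30,-0.01,0.188,ns,0.609,28
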