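target,direction,description,phi,mu,sd,n,n_2015,n_2016,n_2017,n_2018,yield
a,high,B_soil >1113.6 & K_soil >165.5,4.53,0.42,0.45,24,5,3,11,5,58.5
a,high,Ca_soil >196.8 & Zn_soil <=2055.6,4.25,0.5,0.52,19,0,7,4,8,45.1
a,high,K_soil >308.1 & Zn_soil <=2082.0,3.83,0.39,0.51,25,3,6,5,11,49.9
a,high,Fe_soil >324.0 & Fe_soil <=444.0,3.66,0.3,0.56,47,10,12,12,13,49.9
a,high,B_soil <=366.0 & Dryness == 'wet',3.54,0.34,0.48,26,7,1,6,12,50.2
a,low,Dryness == 'average' & Zn_soil >6868.8 & Zn_soil <=11569.2,4.83,-0.79,0.64,15,1,8,3,3,39.5
a,low,S_soil <=22.8 & Dryness != 'wet' & Fe_soil >446.4,4.66,-0.52,0.58,27,10,10,4,3,46.9
a,low,K_soil <=308.1 & Dryness != 'wet' & Nutrient_content == 'poor',4.62,-0.6,0.65,25,5,5,8,7,46.7
a,low,N_soil <=138.2 & Dryness != 'wet' & Nutrient_content == 'poor',4.58,-0.66,0.66,21,4,5,5,7,44.1
a,low,Mn_soil >9234.0 & K_soil <=375.3,4.48,-0.48,0.67,38,8,10,8,12,45.6
b,high,B_soil >564.0 & N_soil >174.2 & K_soil <=183.1,5.18,0.66,0.55,19,5,5,7,2,47.4
b,high,S_soil >11.4 & Dryness == 'average' & K_soil <=166.2,5.15,0.53,0.63,37,8,12,9,8,45.2
b,high,Dryness == 'average' & S_soil >10.0 & K_soil <=166.7,4.84,0.51,0.64,38,9,12,9,8,45.4
b,high,K_soil <=146.1 & Dryness == 'average' & N_soil >101.6,4.62,0.5,0.51,22,8,4,6,4,50.1
b,high,Dryness == 'average' & K_soil <=274.7 & B_soil >453.6,4.58,0.51,0.69,39,11,14,11,3,47.9
b,low,B_soil <=564.0 & Dryness == 'wet',3.43,-0.34,0.66,43,8,8,8,19,44.4
b,low,Dryness == 'wet' & N_soil <=89.8,3.00,-0.3,0.59,35,5,10,13,7,45.4
b,low,Dryness == 'wet' & B_soil <=750.0,2.99,-0.27,0.65,52,9,9,10,24,43.2
b,low,Ca_soil >196.8 & Zn_soil <=2055.6,2.81,-0.35,0.55,19,0,7,4,8,45.1
b,low,Dryness == 'wet' & Zn_soil <=1290.0,2.79,-0.45,0.68,18,2,5,5,6,46.6
c,high,Fe_soil >324.0 & P_soil >6.0,3.43,0.32,0.44,22,10,6,3,3,55.9
c,high,Zn_soil >7294.8 & B_soil <=592.8,3.33,0.26,0.47,36,7,11,6,12,46.7
c,high,K_soil <=146.1 & Ca_soil >14.7,3.01,0.37,0.53,18,0,10,1,7,41.1
c,high,Mn_soil >1454.4 & Mg_soil <=141.5,2.93,0.28,0.58,36,7,11,6,12,44.7
c,high,Zn_soil >3906.0 & Mg_soil <=133.2,2.77,0.27,0.47,24,4,8,3,9,41.5
c,low,N_soil >40.2 & K_soil <=234.0,3.81,-0.21,0.67,146,45,25,42,34,49.2
c,low,N_soil >40.2 & Mg_soil >202.2,3.71,-0.21,0.68,141,37,17,42,45,50.2
c,low,Zn_soil <=3906.0 & Mg_soil >228.0,3.56,-0.24,0.68,104,27,21,24,32,49.8
c,low,Fe_soil <=324.0 & K_soil <=216.3,3.54,-0.24,0.70,109,20,30,31,28,48.9
c,low,K_soil <=146.1 & B_soil >1405.2,3.38,-0.62,0.90,24,4,7,13,0,46.4
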