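subset,treatment,family,predictor,sd,rmsep,bias,sep_b,rpd,r2,n
cropland,SG1,svm,spc,8.6,4.9,0.2,4.9,1.74,0.67,2828
cropland,SG1+SNV,svm,rfe+clay,8.6,4.0,0.1,4.0,2.17,0.79,2828
grassland,SG1,svm,spc,17.4,9.3,-0.9,9.3,1.86,0.71,1383
grassland,SG0,cubist,rfe+sand,17.4,6.4,0.1,6.4,2.70,0.87,1383
woodland,SG1,svm,spc,29.8,15.0,0.8,15.0,1.99,0.75,1564
woodland,SG0,cubist,rfe+sand,29.8,10.3,1.1,10.3,2.88,0.89,1564
mineral,SG1,svm,spc,19.1,8.9,0.2,8.9,2.13,0.78,6053
mineral,SG1,svm,rfe+sand,19.1,7.3,0.1,7.3,2.62,0.86,6053
organic,SG1+SNV,cubist,spc,100.8,50.6,-10.9,49.5,1.99,0.76,368
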