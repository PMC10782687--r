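# Descriptive statistics of the nine observed variables of the published
# triticale anther-culture study (N = 37 regenerants, eight trials A-H).
# sd is the sample (N-1) standard deviation; values exactly as printed
# (note the GSH variance prints as 0.000 at three decimals; sd^2 = 1.6e-7).
variable,description,minimum,maximum,mean,sd,variance,skewness,kurtosis
Cu,Cu(II) concentration in induction medium,0.1,10.0,5.4270,3.5759,12.787,-0.102,-1.008
Ag,Ag(I) concentration in induction medium,0.0,60.0,22.4324,26.7089,713.363,0.704,-1.480
Time,anther culture time (days),35.0,49.0,43.7027,5.8112,33.770,-0.495,-1.371
CHH_DNMV,de novo CHH methylation (metAFLP),0.3600,0.7600,0.5838,0.1370,0.019,-0.194,-1.054
CHH_SV,CHH sequence variation (metAFLP),8.4800,8.9100,8.6546,0.1146,0.013,-0.079,-0.754
LMP,FTIR absorbance 990-950 cm-1 (low-methylated pectins),0.3583,0.9473,0.5512,0.1223,0.015,0.951,1.406
SAM,FTIR absorbance 1630...1470 cm-1 (S-adenosyl-L-methionine),2.6528,4.6522,3.9617,0.4635,0.215,-0.709,0.278
GSH,FTIR absorbance 2550-2540 cm-1 (glutathione),0.0041,0.0060,0.0051,0.0004,0.000,-0.351,0.054
GPRE,green regenerants per 100 plated anthers,0.7140,6.0610,2.5563,1.6589,2.752,0.932,-0.122
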