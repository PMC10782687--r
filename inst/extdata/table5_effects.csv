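# Direct, indirect and total effects of the published model, exactly as
# printed (blank cells printed as "-" are NA here).  One corrupted cell
# ("2.253sss9" on the CHH_SV -> GPRE row) was transcribed as 2.2539, the
# lambda12 estimate it repeats.
target,source,direct_b,indirect_b,total_b,direct_beta,indirect_beta,total_beta
GPRE,LMP,NA,-0.5628,-0.5628,NA,-0.0419,-0.0419
GPRE,Cu,0.3795,-0.0012,0.3782,0.8252,-0.0026,0.8226
GPRE,SAM,-1.0138,0.6314,-0.3824,-0.2858,0.178,-0.1078
GPRE,CHH_DNMV,-3.0603,0.7791,-2.2811,-0.2530,0.0644,-0.1886
GPRE,CHH_SV,2.2539,NA,2.2539,0.1578,NA,0.1578
GPRE,GSH,1535.381,NA,1535.381,0.3908,NA,0.3908
GSH,LMP,NA,0.0008,0.0008,NA,0.2462,0.2462
GSH,Cu,NA,NA,NA,0.3437,NA,0.3437
GSH,SAM,0.0006,NA,0.0006,0.6339,NA,0.6339
CHH_SV,LMP,NA,0.0552,0.0552,NA,0.0586,0.0586
CHH_SV,Cu,-0.0166,0.0039,-0.0127,-0.5158,0.1203,-0.3955
CHH_SV,SAM,NA,0.0375,0.0375,NA,0.1509,0.1509
CHH_SV,CHH_DNMV,0.3457,NA,0.3457,0.4082,NA,0.4082
CHH_DNMV,LMP,NA,0.1546,0.1546,NA,0.1436,0.1436
CHH_DNMV,Cu,0.0112,NA,0.0112,0.2947,NA,0.2947
CHH_DNMV,SAM,0.1084,NA,0.1084,0.3697,NA,0.3697
SAM,LMP,1.4717,NA,1.4717,0.3884,NA,0.3884
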