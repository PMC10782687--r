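# Two-tailed significance flags accompanying table2_correlations.csv:
# "*" p <= 0.05, "**" p <= 0.01, empty = not significant.
variable,Cu,Ag,Time,CHH_DNMV,CHH_SV,LMP,SAM,GSH,GPRE
Cu,,,,,*,,,*,**
Ag,,,,**,,,,,
Time,,,,,**,**,,,
CHH_DNMV,,**,,,,,*,,
CHH_SV,*,,**,,,,,,
LMP,,,**,,,,*,,
SAM,,,,*,,*,,**,
GSH,*,,,,,,**,,**
GPRE,**,,,,,,,**,
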