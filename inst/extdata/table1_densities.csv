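site,area_km2,density_1994,density_2011,n_1994,n_1994_lcl,n_1994_ucl,n_2011,n_2011_lcl,n_2011_ucl
KBNP Itebero-Lulingu,2925,1.926,0.224,5635,2995,10633,655,206,2134
KBNP Nzovu,1921,0.691,0.134,1188,605,2343,258,86,811
KBNP Kasese,716,NA,0.256,NA,NA,NA,183,60,536
CFCB,200,NA,0.122,NA,NA,NA,24,4,147
Tayna-Kisimba-Ikobo,1869,NA,0.289,NA,NA,NA,541,121,2414
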