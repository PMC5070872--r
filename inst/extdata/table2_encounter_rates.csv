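site,year_first,year_final,rate_first,rate_final,printed_decline_per_year,printed_percent_of_original,major_decline,pct_reproducible,per_year_reproducible
KBNP Tshivanga,2000,2014,0.89,1.31,-5.4,147.2,FALSE,TRUE,FALSE
KBNP Kasese,2013,2015,0.19,0.18,2.6,94.7,FALSE,TRUE,TRUE
Usala Forest,2007,2014,1.47,1.37,1,93.1,FALSE,FALSE,TRUE
RGPU east,1995,2014,0.72,0.65,0.5,90.3,FALSE,TRUE,TRUE
RGPU north,1995,2014,0.93,0.17,4.3,18.3,TRUE,TRUE,TRUE
KBNP Nzovu,1994,2014,1.21,0.11,4.6,9.1,TRUE,TRUE,FALSE
KBNP Itebero-Lulingu,1994,2013,2.39,0.09,5.1,3.8,TRUE,TRUE,TRUE
Itombwe Reserve,1996,2014,0.61,0.02,5.4,3.3,TRUE,TRUE,TRUE
Maiko National Park,2005,2014,0.42,0.002,11.1,0.5,TRUE,TRUE,TRUE
Balala Forest,1996,2014,0.17,0.00,5.9,0.0,TRUE,TRUE,FALSE
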