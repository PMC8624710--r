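acronym,membrane,Jss_mean,Kp_e3_mean,LT_mean
[IBU],skin,36.98,0.74,1.17
[ValOMe][IBU],skin,36.37,0.72,1.81
[ValOEt][IBU],skin,43.23,0.86,1.20
[ValOiPr][IBU],skin,43.71,0.87,0.55
[ValOPr][IBU],skin,56.56,1.12,0.83
[ValOBu][IBU],skin,49.73,0.99,0.98
[ValOAm][IBU],skin,55.10,1.09,1.17
[ValOHex][IBU],skin,43.65,0.87,1.89
[ValOHept][IBU],skin,32.47,0.65,1.55
[ValOOct][IBU],skin,23.80,0.47,1.35
[IBU],strat-m,163.45,3.26,1.55
[ValOMe][IBU],strat-m,82.38,1.65,1.06
[ValOEt][IBU],strat-m,77.66,1.54,0.97
[ValOiPr][IBU],strat-m,177.23,3.54,1.33
[ValOPr][IBU],strat-m,205.81,4.09,1.82
[ValOBu][IBU],strat-m,153.29,3.10,1.17
[ValOAm][IBU],strat-m,172.48,3.42,1.28
[ValOHex][IBU],strat-m,50.23,0.99,2.00
[ValOHept][IBU],strat-m,93.98,1.88,2.22
[ValOOct][IBU],strat-m,31.96,0.64,1.95
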