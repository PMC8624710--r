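acronym,name,M_pair,M_active,M_pair_display,chain_length,branched
[IBU],ibuprofen free acid,206.284,206.284,206.28,0,FALSE
[ValOMe][IBU],L-valine methyl ester ibuprofenate,337.458,206.284,337.45,1,FALSE
[ValOEt][IBU],L-valine ethyl ester ibuprofenate,351.485,206.284,351.48,2,FALSE
[ValOiPr][IBU],L-valine isopropyl ester ibuprofenate,365.512,206.284,365.51,3,TRUE
[ValOPr][IBU],L-valine propyl ester ibuprofenate,365.512,206.284,365.51,3,FALSE
[ValOBu][IBU],L-valine butyl ester ibuprofenate,379.539,206.284,379.53,4,FALSE
[ValOAm][IBU],L-valine amyl ester ibuprofenate,393.565,206.284,393.56,5,FALSE
[ValOHex][IBU],L-valine hexyl ester ibuprofenate,405.576,206.284,407.59,6,FALSE
[ValOHept][IBU],L-valine heptyl ester ibuprofenate,421.619,206.284,421.61,7,FALSE
[ValOOct][IBU],L-valine octyl ester ibuprofenate,435.646,206.284,435.64,8,FALSE
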