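compound,odor_threshold,printed_band
Ethyl acetate,7750,0.1-1
Isoamyl acetate,30,0.1-1
Pentyl acetate,43,0.1-1
Ethyl hexanoate,5,>1
Hexyl acetate,670,<0.1
3-Hexen-1-yl acetate,13,>1
Ethyl lactate,154636,<0.1
Isoamyl lactate,/,
3-Hexenyl isobutyrate,/,
2-Hexen-1-ol acetate,/,
Ethyl caprylate,5,>1
Ethyl non-anoate,1300,<0.1
Ethyl caprate,200,>1
Ethyl benzoate,53,>1
Ethyl phenylacetate,155.5,<0.1
Ethyl laurate,500,<0.1
Phenethyl acetate,1800,>1
Ethyl tetradecanoate,2000,<0.1
gamma-Decalactone,1.1,>1
Ethyl palmitate,1000,<0.1
Tetradecalactone,29,0.1-1
gamma-Dodecalactone,0.43,>1
Methyl benzoate,73,0.1-1
Ethanol,950,>1
3-Methyl-1-butanol,7000,0.1-1
1-Hexanol,5200,0.1-1
3-Hexen-1-ol,400,0.1-1
Cyclohexanol,300,
2-Octanol,120,
Cyclohexanemethanol,/,
1-Octanol,800,
"2,3-Butanediol",800,
2-Non-anol,20-50,>1
Benzyl alcohol,600,
Phenylethyl alcohol,20000,<0.1
beta-Ionol,10000,<0.1
Hexanal,5-15,
2-Hexenal,30,
"2,4-Heptadienal",15.4,
Benzaldehyde,2000,<0.1
"2,5-Dimethylbenzaldehyde",200,>1
4-Undecanolide,2.1,0.1-1
3-Octanone,21.4,
Geranylacetone,60,0.1-1
Linalool,25,
beta-Ionone,8.4,>1
Geraniol,0.99,>1
Eugenol,5,>1
1-Hexanoic acid,420,0.1-1
Octanoic acid,500,<0.1
Non-anoic acid,500-800,<0.1
Decanoic acid,1000,<0.1
Benzoic acid,1000,
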