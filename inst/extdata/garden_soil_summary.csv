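# Garden-level soil descriptive statistics, Andalusian urban-garden survey.
# Concentrations mg/kg dry weight; n = samples per garden; <LOD = minimum
# below the detection limit of the field XRF technique.
garden_code,n,param,mean,min,max
UTR,3,pH,7.85,7.84,7.86
UTR,3,As,5.5,4.6,6.1
UTR,3,Cr,22.2,<LOD,25.9
UTR,3,Cu,29.0,23.8,36.9
UTR,3,Ni,30.5,27.8,32.8
UTR,3,Pb,14.3,13.1,16.3
UTR,3,Zn,36.0,20.4,52.2
LUC,3,pH,7.44,7.37,7.49
LUC,3,As,8.2,8.2,8.2
LUC,3,Cr,20.4,<LOD,20.4
LUC,3,Cu,17.9,17.8,18.0
LUC,3,Ni,28.0,<LOD,29.1
LUC,3,Pb,17.2,16.4,18.2
LUC,3,Zn,36.7,27.0,55.3
ALA,15,pH,7.75,7.39,8.02
ALA,15,As,13.8,9.8,18.3
ALA,15,Cr,30.0,20.4,61.5
ALA,15,Cu,45.1,34.4,61.0
ALA,15,Ni,53.9,37.5,68.1
ALA,15,Pb,55.3,39.7,67.1
ALA,15,Zn,94.5,77.2,127.1
ALC,13,pH,7.67,7.49,7.98
ALC,13,As,7.2,<LOD,11.0
ALC,13,Cr,20.8,<LOD,26.0
ALC,13,Cu,93.8,28.0,265.0
ALC,13,Ni,31.9,<LOD,41.0
ALC,13,Pb,18.2,14.0,24.0
ALC,13,Zn,112.3,45.0,247.0
GUA,18,pH,7.93,7.57,8.41
GUA,18,As,9.1,<LOD,19.7
GUA,18,Cr,32.7,<LOD,52.5
GUA,18,Cu,28.3,17.8,46.4
GUA,18,Ni,39.0,<LOD,50.2
GUA,18,Pb,29.4,16.0,64.5
GUA,18,Zn,54.1,36.7,107.7
ELE,2,pH,8.38,8.13,8.63
ELE,2,As,9.1,9.1,9.1
ELE,2,Cr,29.9,28.3,31.5
ELE,2,Cu,21.8,17.8,25.8
ELE,2,Ni,43.2,<LOD,58.9
ELE,2,Pb,27.4,26.4,28.3
ELE,2,Zn,67.8,53.2,82.5
HER,18,pH,7.74,7.28,8.11
HER,18,As,8.6,<LOD,12.5
HER,18,Cr,39.9,<LOD,58.1
HER,18,Cu,38.5,20.0,86.7
HER,18,Ni,37.0,27.5,56.2
HER,18,Pb,18.5,13.4,23.0
HER,18,Zn,80.8,59.1,98.8
MI2,5,pH,7.73,7.66,7.87
MI2,5,As,12.4,10.5,14.8
MI2,5,Cr,39.9,32.6,46.0
MI2,5,Cu,36.2,28.8,59.3
MI2,5,Ni,53.0,35.3,63.1
MI2,5,Pb,55.3,43.1,72.0
MI2,5,Zn,69.8,49.8,97.3
TRI,6,pH,7.85,7.09,8.28
TRI,6,As,6.4,4.6,7.9
TRI,6,Cr,21.5,21.5,21.5
TRI,6,Cu,19.1,17.8,22.1
TRI,6,Ni,42.6,30.4,53.8
TRI,6,Pb,17.1,14.6,23.6
TRI,6,Zn,43.8,35.1,59.3
TOR,3,pH,8.66,8.19,8.90
TOR,3,As,8.4,7.8,9.8
TOR,3,Cr,22.9,<LOD,27.8
TOR,3,Cu,23.0,17.8,27.5
TOR,3,Ni,56.2,49.2,61.0
TOR,3,Pb,27.6,26.6,28.3
TOR,3,Zn,52.6,51.5,53.4
ASO,4,pH,7.53,7.50,7.60
ASO,4,As,14.1,10.2,19.1
ASO,4,Cr,36.7,<LOD,58.7
ASO,4,Cu,55.0,44.1,70.5
ASO,4,Ni,48.9,43.4,55.7
ASO,4,Pb,54.0,23.1,92.9
ASO,4,Zn,90.5,79.2,105.8
LEV,3,pH,7.56,7.07,8.00
LEV,3,As,14.8,13.1,17.5
LEV,3,Cr,45.6,29.5,62.1
LEV,3,Cu,58.7,44.2,87.3
LEV,3,Ni,52.4,45.4,64.6
LEV,3,Pb,57.5,48.5,64.8
LEV,3,Zn,74.6,59.9,98.0
MOR,3,pH,6.97,6.50,7.56
MOR,3,As,9.3,8.4,10.6
MOR,3,Cr,33.7,<LOD,51.4
MOR,3,Cu,69.4,44.5,82.6
MOR,3,Ni,35.2,<LOD,46.8
MOR,3,Pb,33.0,20.2,43.4
MOR,3,Zn,95.2,56.0,132.2
NER,2,pH,6.51,5.96,6.81
NER,2,As,87.2,85.5,88.9
NER,2,Cr,90.5,64.0,117.0
NER,2,Cu,333.1,268.0,398.2
NER,2,Ni,40.7,<LOD,54.0
NER,2,Pb,359.6,283.9,435.4
NER,2,Zn,458.5,433.0,484.0
TIN,5,pH,7.25,6.50,7.75
TIN,5,As,167.8,48.9,608.9
TIN,5,Cr,110.2,53.0,139.2
TIN,5,Cu,155.8,128.5,232.6
TIN,5,Ni,41.3,<LOD,55.0
TIN,5,Pb,346.4,144.2,1079.6
TIN,5,Zn,249.7,207.1,373.0
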