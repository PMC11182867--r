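# Published hazard quotients (unitless) per species x area x element for
# the Andalusian urban-garden survey, kept as printed. A few cells are
# internally inconsistent with the rest of the table (apparent exponent
# slips: onion mining As and Ni, tomato city Ni, pepper city Cd); they are
# retained so that the calibration residual check can flag them. Three
# eggplant Zn cells garbled in extraction were repaired by exponent-run
# consistency against the published means.
species,area,element,hq
chard,mining,As,5.44E-03
chard,mining,B,1.17E-03
chard,mining,Ba,6.37E-04
chard,mining,Cd,1.74E-03
chard,mining,Co,2.37E-03
chard,mining,Cr,8.14E-04
chard,mining,Cu,1.64E-03
chard,mining,Mo,1.36E-03
chard,mining,Ni,1.80E-04
chard,mining,Pb,2.09E-03
chard,mining,Zn,1.06E-03
chard,city,As,1.38E-03
chard,city,B,8.83E-04
chard,city,Ba,8.91E-04
chard,city,Cd,8.50E-04
chard,city,Co,3.83E-03
chard,city,Cr,9.60E-04
chard,city,Cu,1.54E-03
chard,city,Mo,1.34E-03
chard,city,Ni,1.36E-04
chard,city,Pb,6.50E-04
chard,city,Zn,6.81E-04
chard,peri-urban,As,5.64E-04
chard,peri-urban,B,1.02E-03
chard,peri-urban,Ba,2.45E-03
chard,peri-urban,Cd,7.39E-04
chard,peri-urban,Co,2.28E-03
chard,peri-urban,Cr,3.75E-04
chard,peri-urban,Cu,1.36E-03
chard,peri-urban,Mo,4.80E-04
chard,peri-urban,Ni,6.10E-05
chard,peri-urban,Pb,8.33E-04
chard,peri-urban,Zn,7.78E-04
onion,mining,As,4.11E-03
onion,mining,B,1.86E-03
onion,mining,Ba,5.70E-03
onion,mining,Cd,1.16E-03
onion,mining,Co,6.43E-03
onion,mining,Cr,2.55E-03
onion,mining,Cu,4.54E-03
onion,mining,Mo,8.67E-03
onion,mining,Ni,3.68E-03
onion,mining,Pb,3.32E-03
onion,mining,Zn,2.02E-03
onion,city,As,4.28E-04
onion,city,B,1.30E-03
onion,city,Ba,1.02E-03
onion,city,Cd,2.06E-03
onion,city,Co,6.78E-03
onion,city,Cr,3.82E-03
onion,city,Cu,3.57E-03
onion,city,Mo,3.91E-03
onion,city,Ni,7.74E-04
onion,city,Pb,1.69E-03
onion,city,Zn,1.75E-03
onion,peri-urban,As,2.31E-04
onion,peri-urban,B,1.65E-03
onion,peri-urban,Ba,3.85E-04
onion,peri-urban,Cd,9.66E-04
onion,peri-urban,Co,6.49E-03
onion,peri-urban,Cr,7.79E-04
onion,peri-urban,Cu,3.39E-03
onion,peri-urban,Mo,9.96E-04
onion,peri-urban,Ni,3.28E-04
onion,peri-urban,Pb,2.75E-03
onion,peri-urban,Zn,2.75E-03
zucchini,mining,As,7.63E-03
zucchini,mining,B,1.01E-03
zucchini,mining,Ba,7.76E-05
zucchini,mining,Cd,3.68E-04
zucchini,mining,Co,2.45E-03
zucchini,mining,Cr,6.63E-04
zucchini,mining,Cu,3.05E-03
zucchini,mining,Mo,3.03E-03
zucchini,mining,Ni,1.60E-04
zucchini,mining,Pb,1.78E-03
zucchini,mining,Zn,1.68E-03
zucchini,city,As,6.76E-04
zucchini,city,B,6.97E-04
zucchini,city,Ba,1.31E-04
zucchini,city,Cd,3.38E-04
zucchini,city,Co,4.36E-03
zucchini,city,Cr,1.34E-03
zucchini,city,Cu,2.00E-03
zucchini,city,Mo,2.44E-03
zucchini,city,Ni,5.21E-04
zucchini,city,Pb,5.77E-04
zucchini,city,Zn,1.10E-03
zucchini,peri-urban,As,2.65E-04
zucchini,peri-urban,B,1.10E-03
zucchini,peri-urban,Ba,1.26E-04
zucchini,peri-urban,Cd,3.77E-04
zucchini,peri-urban,Co,2.85E-03
zucchini,peri-urban,Cr,2.93E-04
zucchini,peri-urban,Cu,2.20E-03
zucchini,peri-urban,Mo,3.19E-03
zucchini,peri-urban,Ni,7.90E-05
zucchini,peri-urban,Pb,7.91E-04
zucchini,peri-urban,Zn,1.98E-03
tomato,mining,As,7.77E-03
tomato,mining,B,2.16E-03
tomato,mining,Ba,1.17E-04
tomato,mining,Cd,3.11E-03
tomato,mining,Co,4.00E-03
tomato,mining,Cr,2.29E-03
tomato,mining,Cu,8.22E-03
tomato,mining,Mo,4.89E-03
tomato,mining,Ni,4.15E-04
tomato,mining,Pb,1.35E-03
tomato,mining,Zn,3.35E-03
tomato,city,As,7.09E-04
tomato,city,B,1.65E-03
tomato,city,Ba,1.38E-04
tomato,city,Cd,2.92E-03
tomato,city,Co,1.37E-02
tomato,city,Cr,2.40E-03
tomato,city,Cu,5.91E-03
tomato,city,Mo,5.19E-03
tomato,city,Ni,6.39E-03
tomato,city,Pb,2.49E-03
tomato,city,Zn,2.03E-03
tomato,peri-urban,As,1.63E-03
tomato,peri-urban,B,1.71E-03
tomato,peri-urban,Ba,1.50E-04
tomato,peri-urban,Cd,6.89E-03
tomato,peri-urban,Co,1.88E-02
tomato,peri-urban,Cr,1.03E-03
tomato,peri-urban,Cu,7.08E-03
tomato,peri-urban,Mo,4.82E-03
tomato,peri-urban,Ni,2.43E-04
tomato,peri-urban,Pb,2.51E-03
tomato,peri-urban,Zn,2.90E-03
eggplant,mining,As,3.73E-03
eggplant,mining,B,4.74E-04
eggplant,mining,Ba,3.04E-05
eggplant,mining,Cd,6.03E-04
eggplant,mining,Co,3.87E-04
eggplant,mining,Cr,3.35E-04
eggplant,mining,Cu,1.30E-03
eggplant,mining,Mo,5.02E-04
eggplant,mining,Ni,8.55E-05
eggplant,mining,Pb,1.89E-04
eggplant,mining,Zn,4.31E-04
eggplant,city,As,2.24E-03
eggplant,city,B,5.32E-04
eggplant,city,Ba,4.25E-05
eggplant,city,Cd,4.67E-03
eggplant,city,Co,2.41E-03
eggplant,city,Cr,3.97E-04
eggplant,city,Cu,1.31E-03
eggplant,city,Mo,7.82E-04
eggplant,city,Ni,5.88E-05
eggplant,city,Pb,6.59E-04
eggplant,city,Zn,4.54E-04
eggplant,peri-urban,As,2.37E-04
eggplant,peri-urban,B,6.69E-04
eggplant,peri-urban,Ba,4.29E-05
eggplant,peri-urban,Cd,1.60E-03
eggplant,peri-urban,Co,2.36E-03
eggplant,peri-urban,Cr,2.13E-04
eggplant,peri-urban,Cu,2.10E-03
eggplant,peri-urban,Mo,1.01E-03
eggplant,peri-urban,Ni,5.42E-05
eggplant,peri-urban,Pb,4.19E-04
eggplant,peri-urban,Zn,7.94E-04
lettuce,city,As,7.00E-03
lettuce,city,B,1.62E-03
lettuce,city,Ba,9.20E-05
lettuce,city,Cd,3.73E-03
lettuce,city,Co,6.96E-03
lettuce,city,Cr,2.71E-03
lettuce,city,Cu,2.83E-03
lettuce,city,Mo,2.40E-03
lettuce,city,Ni,3.14E-04
lettuce,city,Pb,2.07E-03
lettuce,city,Zn,1.84E-03
lettuce,peri-urban,As,4.01E-03
lettuce,peri-urban,B,2.76E-03
lettuce,peri-urban,Ba,3.87E-04
lettuce,peri-urban,Cd,1.46E-02
lettuce,peri-urban,Co,4.34E-03
lettuce,peri-urban,Cr,1.26E-03
lettuce,peri-urban,Cu,3.76E-03
lettuce,peri-urban,Mo,5.31E-04
lettuce,peri-urban,Ni,1.69E-04
lettuce,peri-urban,Pb,2.69E-03
lettuce,peri-urban,Zn,3.23E-03
pepper,mining,As,1.66E-03
pepper,mining,B,5.09E-04
pepper,mining,Ba,2.86E-05
pepper,mining,Cd,5.55E-04
pepper,mining,Co,1.33E-03
pepper,mining,Cr,4.83E-04
pepper,mining,Cu,1.69E-03
pepper,mining,Mo,4.69E-04
pepper,mining,Ni,1.56E-04
pepper,mining,Pb,2.22E-04
pepper,mining,Zn,4.59E-04
pepper,city,As,1.01E-03
pepper,city,B,5.37E-04
pepper,city,Ba,4.19E-05
pepper,city,Cd,9.15E-03
pepper,city,Co,4.45E-03
pepper,city,Cr,9.05E-04
pepper,city,Cu,1.94E-03
pepper,city,Mo,7.17E-04
pepper,city,Ni,1.92E-04
pepper,city,Pb,7.06E-04
pepper,city,Zn,5.92E-04
pepper,peri-urban,As,3.74E-04
pepper,peri-urban,B,4.96E-04
pepper,peri-urban,Ba,4.17E-05
pepper,peri-urban,Cd,1.89E-03
pepper,peri-urban,Co,7.86E-03
pepper,peri-urban,Cr,3.75E-04
pepper,peri-urban,Cu,2.57E-03
pepper,peri-urban,Mo,2.36E-04
pepper,peri-urban,Ni,1.33E-04
pepper,peri-urban,Pb,9.22E-04
pepper,peri-urban,Zn,8.45E-04
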