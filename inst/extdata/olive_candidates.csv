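name,formula,predicted_rt,msms
Catechol,C6H6O2,5.09,65.0033;81.0346;91.0189;108.0217;109.0295
Hydroxytyrosol,C8H10O3,3.53,81.0347;95.0504;108.0217;123.0453;137.0242
Methyl-catechol,C7H8O2,3.53,67.0191;95.0503;123.0451
Tyrosol,C8H10O2,4.14,106.0417;119.0502;137.0608
L-Malic acid,C4H6O5,1.15,59.0139;71.0139;72.9931;89.0243;115.0034
Quinic acid,C7H12O6,1.41,85.0292;87.0086;93.0343;127.0394;191.0550
Apigenin,C15H10O5,8.23,65.0031;117.0342;149.0238;151.0027;225.0542
Kaempferol,C15H10O6,8.20,65.0032;133.0290;151.0031;175.0395;199.0393
Luteolin,C15H10O6,7.51,65.0032;133.0290;151.0031;175.0395;199.0393
alpha-Linolenic acid,C18H30O2,12.73,277.2168;278.2204
Linoleic acid,C18H32O2,13.23,59.0140;261.2219;279.2330
Oleic acid,C18H34O2,13.77,281.2489;282.2519;283.2552
13-Keto-octadeca-9Z-11E-dienoic acid,C18H30O3,10.29,57.0347;113.0965;179.1068;195.1382;293.2111
9R-hydroxy-10E-12Z-octadecadienoic acid,C18H32O3,12.00,171.1020;195.1382;277.2161;293.2116;295.2266
trans-EKODE-(E)-Ib,C18H30O4,10.07,137.0963;139.1121;155.1069;167.1070;171.1017
9-HpODE,C18H32O4,11.83,127.1112;139.1121;171.1018;185.1176;293.2117
Oleoside methyl ester,C17H24O11,4.54,59.0140;71.0140;101.0242;165.0554;223.0607
8-epikingiside,C17H24O11,4.87,
Secoxyloganin,C17H24O11,4.61,59.0140;71.0135;101.0251;121.0289;165.0554
Comselogoside,C25H28O13,4.48,69.0343;145.0292;163.0393;205.0497;265.0715
Oleuropein,C25H32O13,6.02,59.0139;101.0242;181.0869;275.0917;307.0855
Dihydrooleuropein,C25H36O13,,59.0138;71.0139;151.0758;313.1307;377.1445
Verbascoside,C29H36O15,,113.0247;161.0245;315.1090;461.1670;623.1983
Isoacteoside,C29H36O15,,135.0452;161.0245;315.1102;461.1672;623.1984
Campneoside II,C29H36O16,,151.0397;161.0244;179.0347;459.1504;621.1809
Caffeic acid,C9H8O4,4.80,134.0372;135.0452;179.0352
Gallic acid,C7H6O5,1.80,79.0189;107.0139;125.0244;169.0142
p-Coumaric acid,C9H8O3,5.20,93.0346;117.0346;119.0502;163.0401
Ferulic acid,C10H10O4,5.60,134.0373;149.0608;178.0272;193.0506
Pinoresinol,C20H22O6,7.10,83.0503;151.0401;235.0976;357.1344
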