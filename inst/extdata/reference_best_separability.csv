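area,pair,sensor,wavelength,B,JM,M,TD
1,3112_3111,hyper,48,0.81,1.11,1.27,1.11
1,3115_3111,hyper,236,2.55,140,0.18,2.00
1,3115_3112,hyper,464,2.11,1.36,0.22,2.00
1,3121_3111,hyper,696,0.90,1.19,0.03,2.00
1,3121_3112,hyper,989,0.77,1.07,1.24,1.07
1,3121_3115,hyper,1156,3.79,1.42,0.18,2.00
1,3112_3111,multi,782,0.44,0.71,0.93,0.73
1,3115_3111,multi,2202,0.47,0.75,0.43,1.47
1,3115_3112,multi,2202,0.63,0.93,0.39,1.88
1,3121_3111,multi,1613,0.15,0.27,0.05,0.37
1,3121_3112,multi,864,0.57,0.87,1.07,0.90
1,3121_3115,multi,782,0.32,0.55,0.69,0.72
2,3112_3111,hyper,100,1.00,1.27,0.22,2.00
2,3115_3111,hyper,375,2.07,1.35,0.24,2.00
2,3115_3112,hyper,561,1.71,1.224,0.10,2.00
2,3121_3111,hyper,791,2.41,1.40,0.20,2.00
2,3121_3112,hyper,1021,2.21,1.38,0.11,2.00
2,3121_3115,hyper,1190,0.41,0.67,0.89,0.68
2,3121_3122,hyper,1480,1.25,1.23,0.15,2.00
2,3122_3111,hyper,1985,2.10,1.35,0.24,2.00
2,3122_3112,hyper,2171,1.75,1.25,0.09,2.00
2,3122_3115,hyper,2380,0.88,1.17,1.33,1.18
2,3112_3111,multi,1613,0.20,0.36,0.63,0.36
2,3115_3111,multi,664,0.36,0.60,0.05,1.09
2,3115_3112,multi,664,0.51,0.80,0.03,1.62
2,3121_3111,multi,740,0.31,0.54,0.79,0.54
2,3121_3112,multi,740,0.85,1.15,1.30,1.15
2,3121_3115,multi,782,0.27,0.47,0.73,0.48
2,3121_3122,multi,1613,0.30,0.52,0.77,0.53
2,3122_3111,multi,740,0.61,0.91,1.10,0.92
2,3122_3112,multi,740,1.35,1.28,1.64,1.48
2,3122_3115,multi,782,0.58,0.88,1.07,0.93
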