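scenario,maf1,maf2,p00,p01,p02,p10,p11,p12,p20,p21,p22
1,0.1,0.1,0.493,0.526,0.611,0.531,0.387,0.008,0.522,0.410,0.358
2,0.2,0.1,0.507,0.471,0.485,0.480,0.590,0.532,0.556,0.249,0.482
3,0.2,0.2,0.514,0.467,0.539,0.481,0.544,0.447,0.425,0.674,0.304
4,0.3,0.1,0.513,0.438,0.520,0.494,0.530,0.475,0.456,0.696,0.506
5,0.3,0.2,0.488,0.527,0.478,0.525,0.455,0.458,0.450,0.562,0.814
6,0.3,0.3,0.481,0.525,0.483,0.533,0.468,0.470,0.446,0.513,0.734
7,0.4,0.1,0.484,0.570,0.545,0.501,0.494,0.551,0.535,0.359,0.245
8,0.4,0.2,0.490,0.512,0.565,0.523,0.468,0.395,0.455,0.568,0.668
9,0.4,0.3,0.502,0.499,0.495,0.523,0.472,0.503,0.425,0.588,0.501
10,0.4,0.4,0.476,0.506,0.536,0.535,0.473,0.503,0.449,0.568,0.410
11,0.5,0.1,0.306,0.428,0.322,0.333,0.314,0.198,0.341,0.256,0.595
12,0.5,0.2,0.476,0.521,0.715,0.521,0.472,0.392,0.482,0.536,0.502
13,0.5,0.3,0.500,0.477,0.608,0.520,0.480,0.482,0.459,0.563,0.429
14,0.5,0.4,0.422,0.548,0.531,0.515,0.491,0.492,0.547,0.470,0.485
15,0.5,0.5,0.440,0.522,0.515,0.560,0.484,0.472,0.440,0.509,0.542
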