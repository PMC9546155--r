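class,theta_r,theta_s,alpha,n,ksat,tau
Ss,0.0188,0.4459,0.2095,2.3525,4315,0.5
Su2,0.0188,0.4459,0.1571,2.1775,1928,0.5
Su3,0.024,0.4479,0.1054,1.942,642.7,0.5
Su4,0.024,0.4479,0.07907,1.767,287.1,0.5
Us,0.024,0.4479,0.04989,1.487,79.07,0.5
Uu,0.024,0.4479,0.02805,1.137,15.78,0.5
Sl2,0.0328,0.4511,0.1362,2.1095,1358,0.5
St2,0.0485,0.457,0.1547,2.208,2051,0.5
Sl3,0.045,0.4557,0.1012,1.945,616.6,0.5
Sl4,0.0608,0.4615,0.08615,1.8685,415.9,0.5
Slu,0.0538,0.4589,0.05838,1.6225,136.5,0.5
Uls,0.0538,0.4589,0.04378,1.4475,60.95,0.5
Ut2,0.045,0.4557,0.02951,1.196,19.59,0.5
Ut3,0.0608,0.4615,0.02632,1.1475,15.03,0.5
St3,0.0835,0.47,0.1022,2.003,727.8,0.5
Ls4,0.0835,0.47,0.07236,1.793,276.7,0.5
Ls3,0.0835,0.47,0.05426,1.618,123.6,0.5
Ls2,0.0835,0.47,0.0431,1.478,64.86,0.5
Lu,0.0922,0.4732,0.02956,1.2605,23.28,0.5
Ut4,0.0835,0.47,0.02211,1.072,10,0.5
Ts4,0.115,0.4817,0.07413,1.85,331.1,0.5
Lts,0.1325,0.4882,0.0439,1.555,81.28,0.5
Lt2,0.115,0.4817,0.03508,1.395,40.74,0.5
Tu4,0.115,0.4817,0.01758,1.05,5.888,0.5
Tu3,0.1413,0.4914,0.01794,1.05,6.839,0.5
Ts3,0.15,0.4947,0.05188,1.68,138,0.5
Lt3,0.15,0.4947,0.02455,1.225,16.98,0.5
Ts2,0.2025,0.5142,0.03037,1.425,37.15,0.5
Tl,0.2025,0.5142,0.0215,1.215,14.13,0.5
Tu2,0.2025,0.5142,0.01357,1.05,3.89,0.5
Tt,0.2988,0.5499,0.009042,1.05,1.758,0.5
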