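param,transform,intercept,b_sand,b_clay,b_bd,b_corg,lower,upper
theta_s,identity,0.850,0,0.0013,-0.283,0.006,0.25,0.70
theta_r,identity,0.010,0,0.0035,0,0,0.001,0.30
alpha,log10,-1.30,0.0100,-0.0055,-0.20,0,0.0005,0.50
n,identity,1.070,0.0140,-0.0030,0,-0.010,1.05,3.5
ksat,log10,1.94,0.0280,-0.0100,-0.60,0,0.5,50000
tau,identity,0.5,0,0,0,0,0.5,0.5
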