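class,clay_lo,clay_hi,silt_lo,silt_hi,name
Ss,0,5,0,10,pure sand
Su2,0,5,10,25,slightly silty sand
Su3,0,8,25,40,moderately silty sand
Su4,0,8,40,50,strongly silty sand
Us,0,8,50,80,sandy silt
Uu,0,8,80,100,pure silt
Sl2,5,8,10,25,slightly loamy sand
St2,5,17,0,10,slightly clayey sand
Sl3,8,12,10,40,moderately loamy sand
Sl4,12,17,10,40,strongly loamy sand
Slu,8,17,40,50,silty loamy sand
Uls,8,17,50,65,loamy silt
Ut2,8,12,65,92,slightly clayey silt
Ut3,12,17,65,88,moderately clayey silt
St3,17,25,0,15,moderately clayey sand
Ls4,17,25,15,30,strongly sandy loam
Ls3,17,25,30,40,moderately sandy loam
Ls2,17,25,40,50,slightly sandy loam
Lu,17,30,50,65,silty loam
Ut4,17,25,65,83,strongly clayey silt
Ts4,25,35,0,15,strongly sandy clay
Lts,25,45,15,30,sandy clayey loam
Lt2,25,35,30,50,slightly clayey loam
Tu4,25,35,65,75,strongly silty clay
Tu3,30,45,50,65,moderately silty clay
Ts3,35,45,0,15,moderately sandy clay
Lt3,35,45,30,50,moderately clayey loam
Ts2,45,65,0,15,slightly sandy clay
Tl,45,65,15,30,loamy clay
Tu2,45,65,30,55,slightly silty clay
Tt,65,100,0,35,pure clay
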