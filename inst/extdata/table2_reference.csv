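method,height_mm,angle_mean,angle_sd,r
AM-CT,5,31.8,15.3,0.86
AM-CT,10,26.8,14.9,0.92
AM-3D,5,18.3,12.5,0.71
AM-3D,10,16.9,12.3,0.61
AT-3D,5,45.2,17.5,0.56
AT-3D,10,37.6,15.2,0.57
PSA,NA,29.8,17.7,NA
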