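table,icc,f,pval,ci_lo,ci_hi
1,0.8832357491561363,17.662617408627263,7.339425543835223e-12,0.76,0.94
2,0.8841277165221515,15.756924867884106,3.226760824927298e-11,0.77,0.94
3,0.8161841117631017,11.70911081440922,1.3768943600155156e-09,0.61,0.91
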