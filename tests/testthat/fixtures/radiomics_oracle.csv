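family,feature,value
firstorder,Energy,1314.896181631063
firstorder,TotalEnergy,7100.439380807739
firstorder,Entropy,5.580580252542196
firstorder,Minimum,0.901754
firstorder,10Percentile,0.9811482
firstorder,90Percentile,1.150391
firstorder,Maximum,1.221604
firstorder,Mean,1.0617864692556633
firstorder,Median,1.05999
firstorder,InterquartileRange,0.09121400000000013
firstorder,Range,0.31984999999999997
firstorder,MeanAbsoluteDeviation,0.05375454804620815
firstorder,RobustMeanAbsoluteDeviation,0.038636341261125404
firstorder,RootMeanSquared,2.0628445042329817
firstorder,Skewness,0.10870790661216737
firstorder,Kurtosis,2.488255486886069
firstorder,Variance,0.004364003838482063
firstorder,Uniformity,0.023952409379876624
shape,MeshVolume,1608.075
shape,VoxelVolume,1668.6
shape,SurfaceArea,813.6798195482022
shape,SurfaceVolumeRatio,0.5059961877077886
shape,Sphericity,0.8157707192476201
shape,Maximum3DDiameter,20.144726357039453
shape,Maximum2DDiameterSlice,16.638509548634456
shape,Maximum2DDiameterColumn,15.0
shape,Maximum2DDiameterRow,14.709180806557516
shape,MajorAxisLength,14.261700622063547
shape,MinorAxisLength,13.602109456886545
shape,LeastAxisLength,12.356797189145892
shape,Elongation,0.9537508756735096
shape,Flatness,0.8664322381041517
glcm,Autocorrelation,1127.598342987856
glcm,ClusterProminence,556303.4311485717
glcm,ClusterShade,1186.3540504976252
glcm,ClusterTendency,468.8819468388243
glcm,Contrast,210.54321666728356
glcm,Correlation,0.38019152536428336
glcm,DifferenceAverage,11.659238926850536
glcm,DifferenceEntropy,4.791651390457854
glcm,DifferenceVariance,74.38181433153653
glcm,Id,0.16064911761602657
glcm,Idm,0.08546322665046811
glcm,Idmn,0.9546633817400925
glcm,Idn,0.8562535934765406
glcm,Imc1,-0.4586497849851253
glcm,Imc2,0.9968035748275581
glcm,InverseVariance,0.08603052638809383
glcm,JointAverage,32.60332339568722
glcm,JointEnergy,0.0029004397352895847
glcm,JointEntropy,8.533935528204351
glcm,MaximumProbability,0.009930321940066027
glcm,MCC,0.7088280244335957
glcm,SumAverage,65.20664679137445
glcm,SumEntropy,6.083958373275896
glcm,SumSquares,169.856290876527
glrlm,GrayLevelNonUniformity,7.175140283194029
glrlm,GrayLevelNonUniformityNormalized,0.023745871765000284
glrlm,GrayLevelVariance,175.46815946434603
glrlm,HighGrayLevelRunEmphasis,1232.0491597031455
glrlm,LongRunEmphasis,1.069124548140861
glrlm,LongRunHighGrayLevelEmphasis,1314.994114514359
glrlm,LongRunLowGrayLevelEmphasis,0.005721836709027418
glrlm,LowGrayLevelRunEmphasis,0.005625108787673993
glrlm,RunEntropy,5.672162669217941
glrlm,RunLengthNonUniformity,289.0787444738307
glrlm,RunLengthNonUniformityNormalized,0.9566568147003323
glrlm,RunPercentage,0.9778441623101817
glrlm,RunVariance,0.023168882504045845
glrlm,ShortRunEmphasis,0.9832896163783474
glrlm,ShortRunHighGrayLevelEmphasis,1212.0526174243196
glrlm,ShortRunLowGrayLevelEmphasis,0.005601367203488076
glszm,GrayLevelNonUniformity,5.206896551724138
glszm,GrayLevelNonUniformityNormalized,0.022443519619500595
glszm,GrayLevelVariance,187.10684824613557
glszm,HighGrayLevelZoneEmphasis,1229.1163793103449
glszm,LargeAreaEmphasis,2.564655172413793
glszm,LargeAreaHighGrayLevelEmphasis,3113.012931034483
glszm,LargeAreaLowGrayLevelEmphasis,0.00892121329410583
glszm,LowGrayLevelZoneEmphasis,0.006913626207400853
glszm,SizeZoneNonUniformity,153.3448275862069
glszm,SizeZoneNonUniformityNormalized,0.6609690844233056
glszm,SmallAreaEmphasis,0.8394611037262925
glszm,SmallAreaHighGrayLevelEmphasis,1021.601751260849
glszm,SmallAreaLowGrayLevelEmphasis,0.00668768433675243
glszm,ZoneEntropy,6.180420694660054
glszm,ZonePercentage,0.7508090614886731
glszm,ZoneVariance,0.7907067479191437
ngtdm,Busyness,0.036494913324442886
ngtdm,Coarseness,0.018560102993801363
ngtdm,Complexity,10322.845534109441
ngtdm,Contrast,0.8805670594004339
ngtdm,Strength,21.009989598874473
gldm,DependenceEntropy,6.46615819741066
gldm,DependenceNonUniformity,136.46278317152104
gldm,DependenceNonUniformityNormalized,0.44162713000492243
gldm,DependenceVariance,0.6908180685162493
gldm,GrayLevelNonUniformity,7.401294498381877
gldm,GrayLevelVariance,174.5282516940543
gldm,HighGrayLevelEmphasis,1231.304207119741
gldm,LargeDependenceEmphasis,3.174757281553398
gldm,LargeDependenceHighGrayLevelEmphasis,3773.0064724919093
gldm,LargeDependenceLowGrayLevelEmphasis,0.008604320455966227
gldm,LowGrayLevelEmphasis,0.0055315267115959915
gldm,SmallDependenceEmphasis,0.6802022653721683
gldm,SmallDependenceHighGrayLevelEmphasis,832.0018464581086
gldm,SmallDependenceLowGrayLevelEmphasis,0.005087118145862826
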