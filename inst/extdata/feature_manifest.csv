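"feature","family","name"
"firstorder_Mean","firstorder","Mean"
"firstorder_Median","firstorder","Median"
"firstorder_Minimum","firstorder","Minimum"
"firstorder_Maximum","firstorder","Maximum"
"firstorder_Range","firstorder","Range"
"firstorder_Variance","firstorder","Variance"
"firstorder_Skewness","firstorder","Skewness"
"firstorder_Kurtosis","firstorder","Kurtosis"
"firstorder_Energy","firstorder","Energy"
"firstorder_TotalEnergy","firstorder","TotalEnergy"
"firstorder_Entropy","firstorder","Entropy"
"firstorder_Uniformity","firstorder","Uniformity"
"firstorder_InterquartileRange","firstorder","InterquartileRange"
"firstorder_Percentile10","firstorder","Percentile10"
"firstorder_Percentile90","firstorder","Percentile90"
"firstorder_MeanAbsoluteDeviation","firstorder","MeanAbsoluteDeviation"
"firstorder_RootMeanSquared","firstorder","RootMeanSquared"
"shape2D_MeshSurface","shape2D","MeshSurface"
"shape2D_PixelSurface","shape2D","PixelSurface"
"shape2D_Perimeter","shape2D","Perimeter"
"shape2D_PerimeterSurfaceRatio","shape2D","PerimeterSurfaceRatio"
"shape2D_Sphericity","shape2D","Sphericity"
"shape2D_SphericalDisproportion","shape2D","SphericalDisproportion"
"shape2D_MaximumDiameter","shape2D","MaximumDiameter"
"shape2D_MajorAxisLength","shape2D","MajorAxisLength"
"shape2D_MinorAxisLength","shape2D","MinorAxisLength"
"shape2D_Elongation","shape2D","Elongation"
"shape3D_MeshVolume","shape3D","MeshVolume"
"shape3D_VoxelVolume","shape3D","VoxelVolume"
"shape3D_SurfaceArea","shape3D","SurfaceArea"
"shape3D_SurfaceVolumeRatio","shape3D","SurfaceVolumeRatio"
"shape3D_Sphericity","shape3D","Sphericity"
"shape3D_Maximum3DDiameter","shape3D","Maximum3DDiameter"
"shape3D_MajorAxisLength","shape3D","MajorAxisLength"
"shape3D_MinorAxisLength","shape3D","MinorAxisLength"
"shape3D_LeastAxisLength","shape3D","LeastAxisLength"
"shape3D_Elongation","shape3D","Elongation"
"glcm_Autocorrelation","glcm","Autocorrelation"
"glcm_JointAverage","glcm","JointAverage"
"glcm_ClusterProminence","glcm","ClusterProminence"
"glcm_ClusterShade","glcm","ClusterShade"
"glcm_ClusterTendency","glcm","ClusterTendency"
"glcm_Contrast","glcm","Contrast"
"glcm_Correlation","glcm","Correlation"
"glcm_DifferenceAverage","glcm","DifferenceAverage"
"glcm_DifferenceEntropy","glcm","DifferenceEntropy"
"glcm_DifferenceVariance","glcm","DifferenceVariance"
"glcm_JointEnergy","glcm","JointEnergy"
"glcm_JointEntropy","glcm","JointEntropy"
"glcm_Imc1","glcm","Imc1"
"glcm_Imc2","glcm","Imc2"
"glcm_Idm","glcm","Idm"
"glcm_Id","glcm","Id"
"glcm_Idmn","glcm","Idmn"
"glcm_Idn","glcm","Idn"
"glcm_InverseVariance","glcm","InverseVariance"
"glcm_MaximumProbability","glcm","MaximumProbability"
"glcm_SumAverage","glcm","SumAverage"
"glcm_SumEntropy","glcm","SumEntropy"
"glcm_SumSquares","glcm","SumSquares"
"glcm_MCC","glcm","MCC"
"glrlm_ShortRunEmphasis","glrlm","ShortRunEmphasis"
"glrlm_LongRunEmphasis","glrlm","LongRunEmphasis"
"glrlm_GrayLevelNonUniformity","glrlm","GrayLevelNonUniformity"
"glrlm_RunLengthNonUniformity","glrlm","RunLengthNonUniformity"
"glrlm_RunPercentage","glrlm","RunPercentage"
"glrlm_GrayLevelVariance","glrlm","GrayLevelVariance"
"glrlm_RunVariance","glrlm","RunVariance"
"glrlm_RunEntropy","glrlm","RunEntropy"
"glrlm_LowGrayLevelRunEmphasis","glrlm","LowGrayLevelRunEmphasis"
"glrlm_HighGrayLevelRunEmphasis","glrlm","HighGrayLevelRunEmphasis"
"glrlm_ShortRunHighGrayLevelEmphasis","glrlm","ShortRunHighGrayLevelEmphasis"
"glrlm_LongRunHighGrayLevelEmphasis","glrlm","LongRunHighGrayLevelEmphasis"
"glszm_SmallAreaEmphasis","glszm","SmallAreaEmphasis"
"glszm_LargeAreaEmphasis","glszm","LargeAreaEmphasis"
"glszm_GrayLevelNonUniformity","glszm","GrayLevelNonUniformity"
"glszm_SizeZoneNonUniformity","glszm","SizeZoneNonUniformity"
"glszm_ZonePercentage","glszm","ZonePercentage"
"glszm_GrayLevelVariance","glszm","GrayLevelVariance"
"glszm_ZoneVariance","glszm","ZoneVariance"
"glszm_ZoneEntropy","glszm","ZoneEntropy"
"glszm_LowGrayLevelZoneEmphasis","glszm","LowGrayLevelZoneEmphasis"
"glszm_HighGrayLevelZoneEmphasis","glszm","HighGrayLevelZoneEmphasis"
"glszm_SmallAreaHighGrayLevelEmphasis","glszm","SmallAreaHighGrayLevelEmphasis"
"glszm_LargeAreaLowGrayLevelEmphasis","glszm","LargeAreaLowGrayLevelEmphasis"
"ngtdm_Coarseness","ngtdm","Coarseness"
"ngtdm_Contrast","ngtdm","Contrast"
"ngtdm_Busyness","ngtdm","Busyness"
"ngtdm_Complexity","ngtdm","Complexity"
"ngtdm_Strength","ngtdm","Strength"
"ngtdm_GrayLevelMean","ngtdm","GrayLevelMean"
"ngtdm_GrayLevelVariance","ngtdm","GrayLevelVariance"
"ngtdm_GrayLevelEntropy","ngtdm","GrayLevelEntropy"
"ngtdm_TotalDifference","ngtdm","TotalDifference"
"ngtdm_MeanDifference","ngtdm","MeanDifference"
"ngtdm_DifferenceEntropy","ngtdm","DifferenceEntropy"
"ngtdm_NormalizedTotalDifference","ngtdm","NormalizedTotalDifference"
"gldm_SmallDependenceEmphasis","gldm","SmallDependenceEmphasis"
"gldm_LargeDependenceEmphasis","gldm","LargeDependenceEmphasis"
"gldm_GrayLevelNonUniformity","gldm","GrayLevelNonUniformity"
"gldm_DependenceNonUniformity","gldm","DependenceNonUniformity"
"gldm_DependenceNonUniformityNormalized","gldm","DependenceNonUniformityNormalized"
"gldm_GrayLevelVariance","gldm","GrayLevelVariance"
"gldm_DependenceVariance","gldm","DependenceVariance"
"gldm_DependenceEntropy","gldm","DependenceEntropy"
"gldm_LowGrayLevelEmphasis","gldm","LowGrayLevelEmphasis"
"gldm_HighGrayLevelEmphasis","gldm","HighGrayLevelEmphasis"
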