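"family","feature","name"
"firstorder","Energy","firstorder.Energy"
"firstorder","TotalEnergy","firstorder.TotalEnergy"
"firstorder","Entropy","firstorder.Entropy"
"firstorder","Minimum","firstorder.Minimum"
"firstorder","10Percentile","firstorder.10Percentile"
"firstorder","90Percentile","firstorder.90Percentile"
"firstorder","Maximum","firstorder.Maximum"
"firstorder","Mean","firstorder.Mean"
"firstorder","Median","firstorder.Median"
"firstorder","InterquartileRange","firstorder.InterquartileRange"
"firstorder","Range","firstorder.Range"
"firstorder","MeanAbsoluteDeviation","firstorder.MeanAbsoluteDeviation"
"firstorder","RobustMeanAbsoluteDeviation","firstorder.RobustMeanAbsoluteDeviation"
"firstorder","RootMeanSquared","firstorder.RootMeanSquared"
"firstorder","Skewness","firstorder.Skewness"
"firstorder","Kurtosis","firstorder.Kurtosis"
"firstorder","Variance","firstorder.Variance"
"firstorder","Uniformity","firstorder.Uniformity"
"glcm","Autocorrelation","glcm.Autocorrelation"
"glcm","ClusterProminence","glcm.ClusterProminence"
"glcm","ClusterShade","glcm.ClusterShade"
"glcm","ClusterTendency","glcm.ClusterTendency"
"glcm","Contrast","glcm.Contrast"
"glcm","Correlation","glcm.Correlation"
"glcm","DifferenceAverage","glcm.DifferenceAverage"
"glcm","DifferenceEntropy","glcm.DifferenceEntropy"
"glcm","DifferenceVariance","glcm.DifferenceVariance"
"glcm","Id","glcm.Id"
"glcm","Idm","glcm.Idm"
"glcm","Idmn","glcm.Idmn"
"glcm","Idn","glcm.Idn"
"glcm","Imc1","glcm.Imc1"
"glcm","Imc2","glcm.Imc2"
"glcm","InverseVariance","glcm.InverseVariance"
"glcm","JointAverage","glcm.JointAverage"
"glcm","JointEnergy","glcm.JointEnergy"
"glcm","JointEntropy","glcm.JointEntropy"
"glcm","MCC","glcm.MCC"
"glcm","MaximumProbability","glcm.MaximumProbability"
"glcm","SumAverage","glcm.SumAverage"
"glcm","SumEntropy","glcm.SumEntropy"
"glcm","SumSquares","glcm.SumSquares"
"glrlm","GrayLevelNonUniformity","glrlm.GrayLevelNonUniformity"
"glrlm","GrayLevelNonUniformityNormalized","glrlm.GrayLevelNonUniformityNormalized"
"glrlm","GrayLevelVariance","glrlm.GrayLevelVariance"
"glrlm","HighGrayLevelRunEmphasis","glrlm.HighGrayLevelRunEmphasis"
"glrlm","LongRunEmphasis","glrlm.LongRunEmphasis"
"glrlm","LongRunHighGrayLevelEmphasis","glrlm.LongRunHighGrayLevelEmphasis"
"glrlm","LongRunLowGrayLevelEmphasis","glrlm.LongRunLowGrayLevelEmphasis"
"glrlm","LowGrayLevelRunEmphasis","glrlm.LowGrayLevelRunEmphasis"
"glrlm","RunEntropy","glrlm.RunEntropy"
"glrlm","RunLengthNonUniformity","glrlm.RunLengthNonUniformity"
"glrlm","RunLengthNonUniformityNormalized","glrlm.RunLengthNonUniformityNormalized"
"glrlm","RunPercentage","glrlm.RunPercentage"
"glrlm","RunVariance","glrlm.RunVariance"
"glrlm","ShortRunEmphasis","glrlm.ShortRunEmphasis"
"glrlm","ShortRunHighGrayLevelEmphasis","glrlm.ShortRunHighGrayLevelEmphasis"
"glrlm","ShortRunLowGrayLevelEmphasis","glrlm.ShortRunLowGrayLevelEmphasis"
"glszm","GrayLevelNonUniformity","glszm.GrayLevelNonUniformity"
"glszm","GrayLevelNonUniformityNormalized","glszm.GrayLevelNonUniformityNormalized"
"glszm","GrayLevelVariance","glszm.GrayLevelVariance"
"glszm","HighGrayLevelZoneEmphasis","glszm.HighGrayLevelZoneEmphasis"
"glszm","LargeAreaEmphasis","glszm.LargeAreaEmphasis"
"glszm","LargeAreaHighGrayLevelEmphasis","glszm.LargeAreaHighGrayLevelEmphasis"
"glszm","LargeAreaLowGrayLevelEmphasis","glszm.LargeAreaLowGrayLevelEmphasis"
"glszm","LowGrayLevelZoneEmphasis","glszm.LowGrayLevelZoneEmphasis"
"glszm","SizeZoneNonUniformity","glszm.SizeZoneNonUniformity"
"glszm","SizeZoneNonUniformityNormalized","glszm.SizeZoneNonUniformityNormalized"
"glszm","SmallAreaEmphasis","glszm.SmallAreaEmphasis"
"glszm","SmallAreaHighGrayLevelEmphasis","glszm.SmallAreaHighGrayLevelEmphasis"
"glszm","SmallAreaLowGrayLevelEmphasis","glszm.SmallAreaLowGrayLevelEmphasis"
"glszm","ZoneEntropy","glszm.ZoneEntropy"
"glszm","ZonePercentage","glszm.ZonePercentage"
"glszm","ZoneVariance","glszm.ZoneVariance"
"ngtdm","Busyness","ngtdm.Busyness"
"ngtdm","Coarseness","ngtdm.Coarseness"
"ngtdm","Complexity","ngtdm.Complexity"
"ngtdm","Contrast","ngtdm.Contrast"
"ngtdm","Strength","ngtdm.Strength"
"gldm","DependenceEntropy","gldm.DependenceEntropy"
"gldm","DependenceNonUniformity","gldm.DependenceNonUniformity"
"gldm","DependenceNonUniformityNormalized","gldm.DependenceNonUniformityNormalized"
"gldm","DependenceVariance","gldm.DependenceVariance"
"gldm","GrayLevelNonUniformity","gldm.GrayLevelNonUniformity"
"gldm","GrayLevelVariance","gldm.GrayLevelVariance"
"gldm","HighGrayLevelEmphasis","gldm.HighGrayLevelEmphasis"
"gldm","LargeDependenceEmphasis","gldm.LargeDependenceEmphasis"
"gldm","LargeDependenceHighGrayLevelEmphasis","gldm.LargeDependenceHighGrayLevelEmphasis"
"gldm","LargeDependenceLowGrayLevelEmphasis","gldm.LargeDependenceLowGrayLevelEmphasis"
"gldm","LowGrayLevelEmphasis","gldm.LowGrayLevelEmphasis"
"gldm","SmallDependenceEmphasis","gldm.SmallDependenceEmphasis"
"gldm","SmallDependenceHighGrayLevelEmphasis","gldm.SmallDependenceHighGrayLevelEmphasis"
"gldm","SmallDependenceLowGrayLevelEmphasis","gldm.SmallDependenceLowGrayLevelEmphasis"
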