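block,parameter,label,n,mean,sd,test,compare
cohort_group,ncd64,HC,26,1192.58,537.61,anova,
cohort_group,ncd64,stable,65,1697.89,1056.32,anova,
cohort_group,ncd64,infection,50,9424.08,8574.58,anova,
cohort_group,mhladr,HC,26,2341.27,781.75,anova,
cohort_group,mhladr,stable,65,2728.62,854.87,anova,
cohort_group,mhladr,infection,50,2558.66,1360.77,anova,
cohort_group,cd64_index,HC,26,11.63,4.97,anova,
cohort_group,cd64_index,stable,65,17.60,12.03,anova,
cohort_group,cd64_index,infection,50,88.33,75.69,anova,
cohort_group,si,HC,26,58.86,35.74,anova,
cohort_group,si,stable,65,64.50,32.69,anova,
cohort_group,si,infection,50,488.76,613.43,anova,
pathogen,ncd64,bacterial,26,11361.46,9428.95,anova,
pathogen,ncd64,viral,13,4099.15,5347.64,anova,
pathogen,ncd64,fungal,11,11137.91,7337.20,anova,
pathogen,mhladr,bacterial,26,2426.73,1187.87,anova,
pathogen,mhladr,viral,13,3176.31,1601.28,anova,
pathogen,mhladr,fungal,11,2140.55,1317.32,anova,
pathogen,cd64_index,bacterial,26,102.42,81.11,anova,
pathogen,cd64_index,viral,13,44.75,55.29,anova,
pathogen,cd64_index,fungal,11,106.51,67.89,anova,
pathogen,si,bacterial,26,504.29,376.84,anova,
pathogen,si,viral,13,170.73,262.07,anova,
pathogen,si,fungal,11,827.91,1071.35,anova,
sepsis,ncd64,stable,65,1697.89,1056.32,lsd,sepsis|non_sepsis
sepsis,ncd64,sepsis,19,10265.47,8293.09,lsd,sepsis|non_sepsis
sepsis,ncd64,non_sepsis,31,8908.39,8837.41,lsd,sepsis|non_sepsis
sepsis,mhladr,stable,65,2728.62,854.87,lsd,sepsis|non_sepsis
sepsis,mhladr,sepsis,19,1803.47,1192.66,lsd,sepsis|non_sepsis
sepsis,mhladr,non_sepsis,31,3021.52,1260.32,lsd,sepsis|non_sepsis
sepsis,cd64_index,stable,65,17.60,12.03,lsd,sepsis|non_sepsis
sepsis,cd64_index,sepsis,19,100.47,74.46,lsd,sepsis|non_sepsis
sepsis,cd64_index,non_sepsis,31,80.98,76.68,lsd,sepsis|non_sepsis
sepsis,si,stable,65,64.50,32.69,lsd,sepsis|non_sepsis
sepsis,si,sepsis,19,773.96,868.31,lsd,sepsis|non_sepsis
sepsis,si,non_sepsis,31,313.96,281.34,lsd,sepsis|non_sepsis
longitudinal,d_ncd64,exacerbation,3,143.67,5631.89,t_pooled,exacerbation|non_exacerbation
longitudinal,d_ncd64,non_exacerbation,18,-6309.61,9163.02,t_pooled,exacerbation|non_exacerbation
longitudinal,d_mhladr,exacerbation,3,-1273.33,2049.93,t_pooled,exacerbation|non_exacerbation
longitudinal,d_mhladr,non_exacerbation,18,811.06,1461.78,t_pooled,exacerbation|non_exacerbation
longitudinal,d_si,exacerbation,3,701.67,857.79,t_pooled,exacerbation|non_exacerbation
longitudinal,d_si,non_exacerbation,18,-383.17,458.87,t_pooled,exacerbation|non_exacerbation
longitudinal,d_cd64_index,exacerbation,3,0.33,70.29,t_pooled,exacerbation|non_exacerbation
longitudinal,d_cd64_index,non_exacerbation,18,-52.67,69.44,t_pooled,exacerbation|non_exacerbation
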