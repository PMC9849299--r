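model,protein,gene,group,mean,sd,n,status,lloq
mouse,Abcb1,Abcb1,WT,3.1,1.7,6,quantified,NA
mouse,Abcb1,Abcb1,5xFAD,2.2,1.0,6,quantified,NA
mouse,Abcg2,Abcg2,WT,1.1,0.38,6,quantified,NA
mouse,Abcg2,Abcg2,5xFAD,1.1,0.44,6,quantified,NA
mouse,Abcc1,Abcc1,WT,0.065,0.028,6,quantified,NA
mouse,Abcc1,Abcc1,5xFAD,0.068,0.037,6,quantified,NA
mouse,Abcc4,Abcc4,WT,0.13,0.039,6,quantified,NA
mouse,Abcc4,Abcc4,5xFAD,0.16,0.062,6,quantified,NA
mouse,Abca1,Abca1,WT,0.092,0.052,6,quantified,NA
mouse,Abca1,Abca1,5xFAD,0.097,0.041,6,quantified,NA
mouse,ASCT1,Slc1a4,WT,0.71,0.48,6,quantified,NA
mouse,ASCT1,Slc1a4,5xFAD,1.5,0.36,6,quantified,NA
mouse,GLUT1,Slc2a1,WT,46.0,22.0,6,quantified,NA
mouse,GLUT1,Slc2a1,5xFAD,49.0,21.0,6,quantified,NA
mouse,4F2hc,Slc3a2,WT,0.50,0.16,6,quantified,NA
mouse,4F2hc,Slc3a2,5xFAD,0.72,0.17,6,quantified,NA
mouse,CAT-1,Slc7a1,WT,NA,NA,6,ULQ,0.15
mouse,CAT-1,Slc7a1,5xFAD,NA,NA,6,ULQ,0.15
mouse,LAT1,Slc7a5,WT,0.32,0.14,6,quantified,NA
mouse,LAT1,Slc7a5,5xFAD,0.12,0.05,6,quantified,NA
mouse,MCT1,Slc16a1,WT,0.11,0.07,6,quantified,NA
mouse,MCT1,Slc16a1,5xFAD,0.097,0.047,6,quantified,NA
mouse,RFC,Slc19a1,WT,0.088,0.043,6,quantified,NA
mouse,RFC,Slc19a1,5xFAD,0.099,0.033,6,quantified,NA
mouse,OATP1A4,Slco1a4,WT,0.36,0.19,6,quantified,NA
mouse,OATP1A4,Slco1a4,5xFAD,0.49,0.16,6,quantified,NA
mouse,OATP1C1,Slco1c1,WT,0.14,0.038,6,quantified,NA
mouse,OATP1C1,Slco1c1,5xFAD,0.14,0.045,6,quantified,NA
mouse,OCT1,Slc22a1,WT,NA,NA,6,ULQ,0.15
mouse,OCT1,Slc22a1,5xFAD,NA,NA,6,ULQ,0.15
mouse,OAT3,Slc22a8,WT,0.31,0.17,6,quantified,NA
mouse,OAT3,Slc22a8,5xFAD,0.47,0.28,6,quantified,NA
mouse,FATP1,Slc27a1,WT,0.13,0.068,6,quantified,NA
mouse,FATP1,Slc27a1,5xFAD,0.086,0.043,6,quantified,NA
mouse,ENT1,Slc29a1,WT,0.19,0.10,6,quantified,NA
mouse,ENT1,Slc29a1,5xFAD,0.18,0.13,6,quantified,NA
mouse,gGtp,gGtp,WT,2.9,1.2,6,quantified,NA
mouse,gGtp,gGtp,5xFAD,2.5,0.86,6,quantified,NA
mouse,NaKATPase,NaKATPase,WT,29.0,11.0,6,quantified,NA
mouse,NaKATPase,NaKATPase,5xFAD,26.0,2.8,6,quantified,NA
rat,Abcb1,Abcb1,WT,1.6,0.52,6,quantified,NA
rat,Abcb1,Abcb1,TgF344-AD,2.2,0.61,6,quantified,NA
rat,Abcg2,Abcg2,WT,0.12,0.040,6,quantified,NA
rat,Abcg2,Abcg2,TgF344-AD,0.37,0.18,6,quantified,NA
rat,Abcc1,Abcc1,WT,0.021,0.007,6,quantified,NA
rat,Abcc1,Abcc1,TgF344-AD,0.041,0.004,6,quantified,NA
rat,Abcc4,Abcc4,WT,0.046,0.025,6,quantified,NA
rat,Abcc4,Abcc4,TgF344-AD,0.052,0.034,6,quantified,NA
rat,Abca1,Abca1,WT,0.012,0.009,6,quantified,NA
rat,Abca1,Abca1,TgF344-AD,0.033,0.022,6,quantified,NA
rat,ASCT1,Slc1a4,WT,0.17,0.10,6,quantified,NA
rat,ASCT1,Slc1a4,TgF344-AD,0.20,0.18,6,quantified,NA
rat,GLUT1,Slc2a1,WT,19.0,7.6,6,quantified,NA
rat,GLUT1,Slc2a1,TgF344-AD,20.0,6.5,6,quantified,NA
rat,4F2hc,Slc3a2,WT,0.43,0.22,6,quantified,NA
rat,4F2hc,Slc3a2,TgF344-AD,0.42,0.24,6,quantified,NA
rat,CAT-1,Slc7a1,WT,0.49,0.21,6,quantified,NA
rat,CAT-1,Slc7a1,TgF344-AD,0.53,0.12,6,quantified,NA
rat,LAT1,Slc7a5,WT,NA,NA,6,ULQ,0.020
rat,LAT1,Slc7a5,TgF344-AD,NA,NA,6,ULQ,0.020
rat,MCT1,Slc16a1,WT,NA,NA,6,ULQ,0.10
rat,MCT1,Slc16a1,TgF344-AD,NA,NA,6,ULQ,0.10
rat,RFC,Slc19a1,WT,NA,NA,6,ULQ,0.15
rat,RFC,Slc19a1,TgF344-AD,NA,NA,6,ULQ,0.15
rat,OATP1A4,Slco1a4,WT,NA,NA,6,ULQ,0.015
rat,OATP1A4,Slco1a4,TgF344-AD,NA,NA,6,ULQ,0.015
rat,OATP1C1,Slco1c1,WT,0.13,0.040,6,quantified,NA
rat,OATP1C1,Slco1c1,TgF344-AD,0.11,0.080,6,quantified,NA
rat,OCT1,Slc22a1,WT,NA,NA,6,ULQ,0.15
rat,OCT1,Slc22a1,TgF344-AD,NA,NA,6,ULQ,0.15
rat,OAT3,Slc22a8,WT,0.086,0.053,6,quantified,NA
rat,OAT3,Slc22a8,TgF344-AD,0.089,0.038,6,quantified,NA
rat,FATP1,Slc27a1,WT,0.051,0.038,6,quantified,NA
rat,FATP1,Slc27a1,TgF344-AD,0.22,0.13,6,quantified,NA
rat,ENT1,Slc29a1,WT,0.027,0.018,6,quantified,NA
rat,ENT1,Slc29a1,TgF344-AD,0.020,0.012,6,quantified,NA
rat,gGtp,gGtp,WT,0.61,0.12,6,quantified,NA
rat,gGtp,gGtp,TgF344-AD,0.71,0.11,6,quantified,NA
rat,NaKATPase,NaKATPase,WT,15.0,6.8,6,quantified,NA
rat,NaKATPase,NaKATPase,TgF344-AD,19.0,4.1,6,quantified,NA
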