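model,protein,gene,group,mean,sd,n,status,lloq
mouse,Abcb1,Abcb1,WT,0.13,0.061,14,quantified,NA
mouse,Abcb1,Abcb1,5xFAD,0.15,0.052,12,quantified,NA
mouse,Abcg2,Abcg2,WT,0.46,0.21,14,quantified,NA
mouse,Abcg2,Abcg2,5xFAD,0.51,0.24,12,quantified,NA
mouse,Abcc1,Abcc1,WT,0.16,0.033,14,quantified,NA
mouse,Abcc1,Abcc1,5xFAD,0.16,0.044,12,quantified,NA
mouse,Abcc4,Abcc4,WT,0.019,0.011,14,quantified,NA
mouse,Abcc4,Abcc4,5xFAD,0.026,0.011,12,quantified,NA
mouse,Abca1,Abca1,WT,0.12,0.077,14,quantified,NA
mouse,Abca1,Abca1,5xFAD,0.18,0.13,12,quantified,NA
mouse,ASCT1,Slc1a4,WT,3.1,1.6,14,quantified,NA
mouse,ASCT1,Slc1a4,5xFAD,5.9,2.5,12,quantified,NA
mouse,GLUT1,Slc2a1,WT,3.5,1.6,14,quantified,NA
mouse,GLUT1,Slc2a1,5xFAD,3.8,1.3,12,quantified,NA
mouse,4F2hc,Slc3a2,WT,0.81,0.31,14,quantified,NA
mouse,4F2hc,Slc3a2,5xFAD,0.96,0.38,12,quantified,NA
mouse,CAT-1,Slc7a1,WT,NA,NA,14,ULQ,0.15
mouse,CAT-1,Slc7a1,5xFAD,NA,NA,12,ULQ,0.15
mouse,LAT1,Slc7a5,WT,0.73,0.26,14,quantified,NA
mouse,LAT1,Slc7a5,5xFAD,0.61,0.18,12,quantified,NA
mouse,MCT1,Slc16a1,WT,NA,NA,14,ULQ,0.10
mouse,MCT1,Slc16a1,5xFAD,NA,NA,12,ULQ,0.10
mouse,RFC,Slc19a1,WT,NA,NA,14,ULQ,0.15
mouse,RFC,Slc19a1,5xFAD,NA,NA,12,ULQ,0.15
mouse,OATP1A4,Slco1a4,WT,NA,NA,14,ULQ,0.015
mouse,OATP1A4,Slco1a4,5xFAD,NA,NA,12,ULQ,0.015
mouse,OATP1C1,Slco1c1,WT,NA,NA,14,ULQ,0.015
mouse,OATP1C1,Slco1c1,5xFAD,NA,NA,12,ULQ,0.015
mouse,OCT1,Slc22a1,WT,NA,NA,14,ULQ,0.15
mouse,OCT1,Slc22a1,5xFAD,NA,NA,12,ULQ,0.15
mouse,OAT3,Slc22a8,WT,NA,NA,14,ULQ,0.15
mouse,OAT3,Slc22a8,5xFAD,NA,NA,12,ULQ,0.15
mouse,FATP1,Slc27a1,WT,0.66,0.39,14,quantified,NA
mouse,FATP1,Slc27a1,5xFAD,0.83,0.41,12,quantified,NA
mouse,ENT1,Slc29a1,WT,NA,NA,14,ULQ,0.03
mouse,ENT1,Slc29a1,5xFAD,NA,NA,12,ULQ,0.03
mouse,NaKATPase,NaKATPase,WT,72.0,11.0,14,quantified,NA
mouse,NaKATPase,NaKATPase,5xFAD,72.0,16.0,12,quantified,NA
rat,Abcb1,Abcb1,WT,0.19,0.059,5,quantified,NA
rat,Abcb1,Abcb1,TgF344-AD,0.17,0.063,8,quantified,NA
rat,Abcg2,Abcg2,WT,0.038,0.028,5,quantified,NA
rat,Abcg2,Abcg2,TgF344-AD,0.039,0.019,8,quantified,NA
rat,Abcc1,Abcc1,WT,0.071,0.024,5,quantified,NA
rat,Abcc1,Abcc1,TgF344-AD,0.062,0.018,8,quantified,NA
rat,Abcc4,Abcc4,WT,NA,NA,5,ULQ,0.010
rat,Abcc4,Abcc4,TgF344-AD,NA,NA,8,ULQ,0.010
rat,Abca1,Abca1,WT,0.031,0.012,5,quantified,NA
rat,Abca1,Abca1,TgF344-AD,0.028,0.0081,8,quantified,NA
rat,ASCT1,Slc1a4,WT,0.12,0.0029,5,quantified,NA
rat,ASCT1,Slc1a4,TgF344-AD,0.075,0.031,8,quantified,NA
rat,GLUT1,Slc2a1,WT,2.6,0.14,5,quantified,NA
rat,GLUT1,Slc2a1,TgF344-AD,1.8,0.35,8,quantified,NA
rat,4F2hc,Slc3a2,WT,0.53,0.13,5,quantified,NA
rat,4F2hc,Slc3a2,TgF344-AD,0.33,0.13,8,quantified,NA
rat,CAT-1,Slc7a1,WT,NA,NA,5,ULQ,0.15
rat,CAT-1,Slc7a1,TgF344-AD,NA,NA,8,ULQ,0.15
rat,LAT1,Slc7a5,WT,0.065,0.023,5,quantified,NA
rat,LAT1,Slc7a5,TgF344-AD,0.053,0.021,8,quantified,NA
rat,MCT1,Slc16a1,WT,NA,NA,5,ULQ,0.10
rat,MCT1,Slc16a1,TgF344-AD,NA,NA,8,ULQ,0.10
rat,RFC,Slc19a1,WT,NA,NA,5,ULQ,0.15
rat,RFC,Slc19a1,TgF344-AD,NA,NA,8,ULQ,0.15
rat,OATP1A4,Slco1a4,WT,0.16,0.14,5,quantified,NA
rat,OATP1A4,Slco1a4,TgF344-AD,0.098,0.069,8,quantified,NA
rat,OATP1C1,Slco1c1,WT,0.072,0.035,5,quantified,NA
rat,OATP1C1,Slco1c1,TgF344-AD,0.041,0.037,8,quantified,NA
rat,OCT1,Slc22a1,WT,NA,NA,5,ULQ,0.15
rat,OCT1,Slc22a1,TgF344-AD,NA,NA,8,ULQ,0.15
rat,OAT3,Slc22a8,WT,NA,NA,5,ULQ,0.15
rat,OAT3,Slc22a8,TgF344-AD,NA,NA,8,ULQ,0.15
rat,FATP1,Slc27a1,WT,0.74,0.21,5,quantified,NA
rat,FATP1,Slc27a1,TgF344-AD,0.76,0.33,8,quantified,NA
rat,ENT1,Slc29a1,WT,NA,NA,5,ULQ,0.010
rat,ENT1,Slc29a1,TgF344-AD,NA,NA,8,ULQ,0.010
rat,NaKATPase,NaKATPase,WT,46.0,10.1,5,quantified,NA
rat,NaKATPase,NaKATPase,TgF344-AD,61.0,14.0,8,quantified,NA
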