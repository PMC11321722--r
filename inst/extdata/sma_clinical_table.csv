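subject_id,age_group,age,onset_age,time_since_onset,sex,height_cm,weight_kg,smn2_ex7,smn2_ex8,smn1_ex7,smn1_ex8,rhs,tasks
1501(1),Children,2.12,2,0.12,M,83,9.53,NA,NA,NA,NA,NA,W
1501(2),Children,2.56,2,0.56,M,NA,NA,NA,NA,NA,NA,NA,W
1605,Children,11.5,0.5,11,F,118,20.5,3,3,0,0,NA,W
1701,Children,5.48,0.58,4.9,M,117,26.89,3,3,0,0,6.5 (8.5),A
1702,Children,3.67,0.5,3.17,M,95,13.71,3,3,0,0,1.5 (2),A
1703,Children,12.0,0.5,11.5,F,128,19.96,3,3,0,0,9,A
1704,Children,5.92,0.25,5.67,F,107,15.84,3,3,0,0,9,A
1705,Children,3.77,0.33,3.43,F,95,13.68,3,3,0,0,2,A
1706,Children,2.01,0.08,1.93,M,79,9.27,3,3,0,0,3,A
1710,Children,3.67,0.58,3.08,M,87,16.4,3,3,0,0,1,A
1711,Children,7.50,1.25,6.25,F,130,37.63,3,3,0,0,40.75 (41),"W, A"
1712,Children,7.50,1.33,6.17,F,116,25.06,2,2,0,0,48,"W, A"
1713,Children,2.92,0.83,2.08,F,88,11.31,3,3,0,0,8.5,A
1714,Children,1.95,0.25,1.7,M,83,9.49,3,3,0,0,0,A
1715,Children,3.58,1,2.58,F,90,13.2,3,2,0,1,13,A
1716,Children,3.83,0.75,3.08,M,96,16.65,3,3,0,0,4.75,A
1717,Children,6.50,1,5.5,F,108,17.85,3,2,0,1,17.5,A
1602,Adult,20.5,0.75,19.75,F,142,40,3,3,0,0,NA,W
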