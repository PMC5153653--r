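animal_id,group,stage,age_class,clone_status,genotype,sex,age,R,F,G,S,C,A,I
955,foetus_AI,foetus,perinatal,AI,NA,F,GD267,R0,F2,G2,S0,C0,A1,I0
964,foetus_AI,foetus,perinatal,AI,NA,M,GD267,R0,F0,G2,S0,C0,A1,I0
972,foetus_AI,foetus,perinatal,AI,NA,M,GD266,R0,F0,G2,S0,C0,A1,I0
979,foetus_AI,foetus,perinatal,AI,NA,F,GD266,R0,F0,G2,S0,C0,A3,I0
92,foetus_clone,foetus,perinatal,clone,5538,F,GD263,R2,F3,G0,S0,C1,A0,I0
411,foetus_clone,foetus,perinatal,clone,2251,F,GD268,R2,F3,G0,S1,C2,A1,I0
828,foetus_clone,foetus,perinatal,clone,2251,F,GD263,R2,F3,G2,S0,C1,A2,I0
3302,foetus_clone,foetus,perinatal,clone,5538,F,GD257,R2,F3,G0,S1,C2,A2,I0
3303,foetus_clone,foetus,perinatal,clone,5538,F,GD273,R2,F2,G0,S1,C0,A2,I0
3304,foetus_clone,foetus,perinatal,clone,5538,F,GD273,R2,F0,G0,S2,C2,A2,I0
1171,calf_AI,calf,perinatal,AI,NA,F,PD4,R1,F0,G0,S2,C0,A1,I0
1226,calf_AI,calf,perinatal,AI,NA,F,PD4,R0,F0,G2,S0,C0,A0,I0
3594,calf_AI,calf,perinatal,AI,NA,F,PD4,R0,F0,G2,S0,C0,A1,I0
40,calf_clone,calf,perinatal,clone,5538,F,Term(GD279),R0,F0,G2,S0,C0,A0,I0
61,calf_clone,calf,perinatal,clone,5538,F,Term(GD281),R0,F0,G2,S0,C0,A0,I0
76,calf_clone,calf,perinatal,clone,5538,F,PD2,NA,NA,NA,NA,NA,NA,NA
406,calf_clone,calf,perinatal,clone,2251,F,Term(GD281),R1,F3,G2,S0,C2,A0,I0
2263,calf_clone,calf,perinatal,clone,5538,F,PD4,NA,NA,NA,NA,NA,NA,NA
2,adult_AI,adult,adult,AI,NA,F,10y,R0,F0,G0,S0,C0,A0,I1
29,adult_AI,adult,adult,AI,0029,F,10y,R1,F0,G0,S0,C0,A0,I0
229,adult_AI,adult,adult,AI,NA,F,8y,NA,NA,NA,NA,NA,NA,NA
428,adult_AI,adult,adult,AI,NA,F,6y,R0,F0,G0,S0,C0,A1,I0
449,adult_AI,adult,adult,AI,NA,F,6y,R0,F0,G0,S0,C0,A0,I1
460,adult_AI,adult,adult,AI,NA,F,6y,R1,F2,G0,S0,C0,A2,I1
578,adult_AI,adult,adult,AI,NA,F,5y,R0,F0,G0,S0,C0,A0,I1
2353,adult_AI,adult,adult,AI,NA,F,7y,NA,NA,NA,NA,NA,NA,NA
5538,adult_AI,adult,adult,AI,5538,F,15y,R1,F2,G0,S0,C0,A1,I0
139,adult_clone,adult,adult,clone,7711,F,11y,NA,NA,NA,NA,NA,NA,NA
248,adult_clone,adult,adult,clone,5538,F,6y,R0,F2,G0,S0,C0,A0,I2
437,adult_clone,adult,adult,clone,0029,F,6y,R0,F2,G0,S0,C0,A0,I1
439,adult_clone,adult,adult,clone,2251,F,4y,R0,F2,G0,S0,C0,A0,I0
447,adult_clone,adult,adult,clone,0029,F,5y,R0,F0,G0,S0,C0,A0,I0
468,adult_clone,adult,adult,clone,5538,F,5y,R0,F2,G0,S0,C0,A1,I2
474,adult_clone,adult,adult,clone,2251,F,8.5y,NA,NA,NA,NA,NA,NA,NA
477,adult_clone,adult,adult,clone,5538,F,3.5y,R0,F2,G0,S0,C0,A0,I1
512,adult_clone,adult,adult,clone,5538,F,3y,R0,F2,G2,S0,C0,A0,I1
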