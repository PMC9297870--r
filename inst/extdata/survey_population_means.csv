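row_id,region,population_id,location,n,epsps_mean,epsps_se,type1_mean,type1_se,type2_mean,type2_se,mge_mean,mge_se,p_A,p_B,p_C,p_S
1,Pacific Northwest,ID1R,Idaho,4,4.7,2.0,0.0,NA,0.0,NA,4.9,0.5,0.0,0.0,0.5,0.5
2,Pacific Northwest,OR1R-5R,Oregon,5,3.6,0.4,0.0,NA,0.0,NA,5.2,1.2,0.0,0.0,1.0,0.0
3,Central Great Plains,CO1R,Colorado,5,10.3,0.8,11.9,0.8,3.9,0.5,22.5,1.4,1.0,0.0,0.0,0.0
4,Central Great Plains,CO2R,Colorado,3,0.8,0.1,0.0,NA,0.0,NA,3.5,1.6,0.0,0.0,0.0,1.0
5,Central Great Plains,CO3R,Colorado,9,2.6,0.4,0.9,0.7,0.4,0.2,13.8,1.4,0.2,0.6,0.0,0.2
6,Central Great Plains,CO4R,Colorado,3,8.7,0.6,10.8,0.7,3.2,0.2,20.9,1.6,1.0,0.0,0.0,0.0
7,Central Great Plains,CO5R,Colorado,3,6.9,1.6,10.1,2.2,3.0,0.7,24.5,6.2,1.0,0.0,0.0,0.0
8,Central Great Plains,CO6R,Colorado,3,1.1,0.1,0.0,NA,0.0,NA,6.3,0.3,0.0,0.0,0.0,1.0
9,Central Great Plains,CO9S,Colorado,3,1.0,0.0,0.0,NA,0.0,NA,56.0,0.1,0.0,0.0,0.0,1.0
10,Central Great Plains,KS12R,Kansas,6,6.4,1.3,8.1,1.7,2.6,0.5,17.1,3.4,1.0,0.0,0.0,0.0
11,Central Great Plains,KS3R,Kansas,6,7.0,0.7,8.2,1.0,2.4,0.4,16.6,0.8,1.0,0.0,0.0,0.0
12,Central Great Plains,KS4R,Kansas,7,5.1,3.1,5.9,3.1,2.6,1.6,10.4,1.7,0.6,0.0,0.0,0.4
13,Central Great Plains,KS5S,Kansas,5,2.0,0.9,1.4,1.4,0.4,0.4,6.1,2.3,0.2,0.0,0.0,0.8
14,Central Great Plains,KS6S,Kansas,8,4.8,0.9,9.2,1.3,3.0,0.4,20.4,2.2,1.0,0.0,0.0,0.0
15,Central Great Plains,KS9R,Kansas,2,5.9,3.8,5.9,3.8,3.8,0.2,3.2,0.3,1.0,0.0,0.0,0.0
16,Central Great Plains,OK1R,Oklahoma,7,5.9,1.6,7.4,2.3,2.4,0.8,15.2,3.3,0.7,0.0,0.0,0.3
17,Central Great Plains,SBK-11,Colorado,3,8.3,0.8,11.6,0.6,3.1,0.0,20.9,0.5,1.0,0.0,0.0,0.0
18,Central Great Plains,SBK-14,Nebraska,2,4.3,0.1,5.5,0.0,1.7,0.0,12.4,2.4,1.0,0.0,0.0,0.0
19,Central Great Plains,SBK-14,Nebraska,1,0.7,NA,0.0,NA,0.0,NA,3.6,NA,0.0,0.0,0.0,1.0
20,Central Great Plains,SBK-20,Nebraska,3,5.8,2.7,6.4,3.6,2.1,1.2,16.6,4.9,0.7,0.0,0.0,0.3
21,Central Great Plains,SBK-22,Colorado,9,3.4,0.7,3.8,1.8,1.2,0.6,15.3,3.7,0.4,0.0,0.3,0.2
22,Central Great Plains,SBK-9,Colorado,6,1.9,0.3,0.0,NA,0.0,NA,10.3,1.9,0.0,0.7,0.0,0.3
23,Central Great Plains,TX1R,Texas,2,8.9,1.0,9.0,3.4,3.0,0.8,20.9,3.5,1.0,0.0,0.0,0.0
24,Central Great Plains,TX2R,Texas,3,7.6,0.9,9.3,0.5,3.8,0.4,21.6,2.3,1.0,0.0,0.0,0.0
25,Central Great Plains,TX3R,Texas,3,5.3,0.8,4.6,0.1,1.7,0.1,13.2,0.6,1.0,0.0,0.0,0.0
26,Central Great Plains,TX4R,Texas,4,9.7,2.0,9.6,2.3,3.4,0.8,19.7,2.1,1.0,0.0,0.0,0.0
27,Central Great Plains,TX5R,Texas,5,8.3,2.0,8.6,1.6,3.7,0.7,18.2,3.1,1.0,0.0,0.0,0.0
28,Northern Plains,AB1R,Canada,14,5.9,0.8,0.0,NA,0.0,NA,16.6,2.5,0.0,0.6,0.3,0.1
29,Northern Plains,Beaverton,Montana,2,18.8,3.7,0.0,NA,0.0,NA,31.6,2.0,0.0,1.0,0.0,0.0
30,Northern Plains,Billings,Montana,10,15.4,0.6,0.0,NA,0.0,NA,25.8,1.7,0.0,1.0,0.0,0.0
31,Northern Plains,C_8,Montana,6,9.4,0.8,0.0,NA,0.0,NA,20.6,1.7,0.0,1.0,0.0,0.0
32,Northern Plains,C4,Montana,1,6.5,NA,0.0,NA,0.0,NA,11.6,NA,0.0,1.0,0.0,0.0
33,Northern Plains,Carter,Montana,8,5.6,1.3,0.0,NA,0.0,NA,10.3,2.2,0.0,0.6,0.4,0.0
34,Northern Plains,Charlis,Montana,2,15.6,6.2,0.0,NA,0.0,NA,21.3,5.9,0.0,1.0,0.0,0.0
35,Northern Plains,Cropland,Montana,2,30.1,1.3,0.0,NA,0.0,NA,81.1,13.9,0.0,1.0,0.0,0.0
36,Northern Plains,Cut Bank,Montana,3,5.6,1.5,0.0,NA,0.0,NA,15.6,4.4,0.0,1.0,0.0,0.0
37,Northern Plains,Denton,Montana,3,4.9,1.7,0.0,NA,0.0,NA,14.3,5.2,0.0,0.7,0.3,0.0
38,Northern Plains,GIL,Montana,8,11.1,1.6,0.0,NA,0.0,NA,15.8,2.5,0.0,0.75,0.25,0.0
39,Northern Plains,Greg,Montana,3,13.2,4.5,0.0,NA,0.0,NA,35.4,9.1,0.0,1.0,0.0,0.0
40,Northern Plains,Haven,Montana,4,16.6,2.0,0.0,NA,0.0,NA,54.2,5.0,0.0,1.0,0.0,0.0
41,Northern Plains,SBK-29,Montana,2,0.8,0.1,0.0,NA,0.0,NA,9.9,2.5,0.0,0.0,0.0,1.0
42,Northern Plains,SBK-31,Wyoming,6,3.5,0.9,0.0,NA,0.0,NA,4.8,0.6,0.0,0.0,0.7,0.3
43,Northern Plains,SBK-41,Montana,2,0.7,0.1,0.0,NA,0.0,NA,4.5,0.5,0.0,0.0,0.0,1.0
44,Northern Plains,SBK-42,Montana,2,0.7,0.0,0.0,NA,0.0,NA,4.8,0.9,0.0,0.0,0.0,1.0
45,Northern Plains,Teton,Montana,1,20.2,NA,0.0,NA,0.0,NA,31.4,NA,0.0,1.0,0.0,0.0
46,Northern Plains,Vida,Montana,2,16.3,2.1,0.0,NA,0.0,NA,8.4,0.8,0.0,0.0,1.0,0.0
47,Northern Plains,Wild,Montana,3,7.8,1.1,0.0,NA,0.0,NA,16.4,2.2,0.0,0.0,1.0,0.0
48,Northern Plains,WY1R,Wyoming,3,6.8,0.9,0.0,NA,0.0,NA,7.7,2.6,0.0,0.3,0.7,0.0
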