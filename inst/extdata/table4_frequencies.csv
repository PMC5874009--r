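trait,breakpoint,in_mmd,measure,MV,MVL,MVNL,BRIT,MunRain,HalD,LAA,LAB,LAC,ETB,ETC,PCB,PCC,CAA,CAB,CAC,SUL,SAM,MON
Double shovel UI1,ASU 2-6,TRUE,percent,11.1,0.0,20.0,0.0,0.0,0.0,12.5,0.0,0.0,16.7,9.1,15.6,0.0,14.3,0.0,4.8,8.3,3.3,0.0
Double shovel UI1,ASU 2-6,TRUE,n,18,7,10,31,33,30,8,5,19,6,11,32,41,14,7,21,12,30,9
Interruption groove UI2,ASU +,FALSE,percent,44.4,85.7,20.0,38.7,30.3,40.0,66.7,75.0,63.6,54.5,70.8,77.5,65.8,63.2,90.9,30.4,58.3,65.5,64.7
Interruption groove UI2,ASU +,FALSE,n,18,7,10,31,33,30,9,8,22,11,24,40,73,19,11,23,12,58,17
Tuberculum dentale UI2,ASU 2-6,TRUE,percent,47.1,57.1,44.4,58.1,60.6,30.0,66.7,42.9,65.4,50.0,43.5,62.2,57.5,65.0,53.8,24.0,60.0,50.0,58.8
Tuberculum dentale UI2,ASU 2-6,TRUE,n,17,7,9,31,33,30,9,7,26,10,23,45,80,20,13,25,10,50,17
Distal accessory ridge UC,ASU 2-5,TRUE,percent,25.0,33.3,20.0,29.0,57.6,33.3,33.3,62.5,70.4,81.8,58.3,73.0,66.1,92.9,60.0,66.7,63.6,74.3,57.1
Distal accessory ridge UC,ASU 2-5,TRUE,n,8,3,5,31,33,30,9,8,27,11,12,37,59,14,5,15,11,35,14
Carabelli's trait UM1,ASU 2-7,TRUE,percent,43.8,71.4,25.0,25.8,24.2,10.0,71.4,62.5,78.6,58.2,50.0,58.2,62.8,70.8,53.8,48.3,37.5,71.7,63.2
Carabelli's trait UM1,ASU 2-7,TRUE,n,16,7,8,31,33,30,14,16,42,12,20,55,94,24,13,29,16,60,19
Parastyle UM3,ASU 1-5,TRUE,percent,15.4,0.0,40.0,25.8,27.3,20.0,40.0,6.7,10.0,0.0,10.0,23.8,20.3,30.0,9.1,13.8,0.0,8.2,0.0
Parastyle UM3,ASU 1-5,TRUE,n,13,7,5,31,33,30,10,15,40,18,20,42,69,20,11,29,12,49,20
Premolar root number UP1,ASU 2+,TRUE,percent,42.9,60.0,37.5,32.3,27.3,43.3,50.0,60.0,0.0,73.3,57.1,63.6,69.8,47.1,81.8,47.4,63.6,78.3,52.6
Premolar root number UP1,ASU 2+,TRUE,n,14,5,8,31,33,30,6,10,2,15,28,55,86,17,11,19,22,46,19
Molar root number UM2,ASU 3+,TRUE,percent,94.1,100.0,88.9,35.5,30.3,63.3,70.0,62.5,75.0,73.7,69.6,72.9,69.1,84.2,84.2,69.2,44.4,73.5,61.1
Molar root number UM2,ASU 3+,TRUE,n,17,7,9,31,33,30,10,8,4,19,23,48,81,19,19,13,18,49,18
Lingual cusp LP2,ASU 2-9,TRUE,percent,72.2,75.0,77.8,61.3,27.3,23.3,50.0,41.7,54.3,24.0,39.4,43.8,46.2,65.0,58.3,37.8,58.3,62.7,36.8
Lingual cusp LP2,ASU 2-9,TRUE,n,18,8,9,31,33,30,12,12,35,25,33,48,65,20,12,37,12,59,19
Groove pattern LM2,ASU Y,TRUE,percent,7.1,12.5,0.0,6.5,0.0,36.7,26.7,44.4,27.8,33.3,19.6,28.1,23.6,39.4,23.5,15.2,13.6,12.7,16.0
Groove pattern LM2,ASU Y,TRUE,n,14,8,5,31,33,30,15,18,36,36,51,64,110,33,17,33,22,63,25
Cusp number LM1,ASU 6+,TRUE,percent,0.0,0.0,0.0,6.5,0.0,16.7,0.0,6.2,8.1,3.2,2.2,2.3,3.2,12.1,0.0,0.0,9.1,1.4,0.0
Cusp number LM1,ASU 6+,TRUE,n,18,8,9,31,33,30,13,14,34,31,45,44,93,33,16,25,22,69,23
Deflecting wrinkle LM1,ASU 2-3,FALSE,percent,0.0,0.0,0.0,25.8,54.5,20.0,12.5,10.0,10.0,0.0,12.5,11.4,15.6,21.1,0.0,25.0,11.1,5.0,12.5
Deflecting wrinkle LM1,ASU 2-3,FALSE,n,2,0,2,31,33,30,8,10,20,15,8,35,45,19,5,8,9,20,8
Trigonid crest LM1,ASU +,FALSE,percent,0.0,0.0,0.0,29.0,42.4,16.7,0.0,7.7,6.7,5.9,7.7,4.3,11.1,0.0,0.0,16.7,8.3,2.9,0.0
Trigonid crest LM1,ASU +,FALSE,n,4,3,1,31,33,30,9,13,30,17,13,46,63,26,8,12,12,35,19
Protostylid LM1,ASU 1-6,FALSE,percent,6.7,0.0,14.3,19.4,27.3,23.3,81.8,85.7,74.2,62.5,48.5,74.5,75.3,65.4,63.6,10.5,58.8,65.9,93.8
Protostylid LM1,ASU 1-6,FALSE,n,15,7,7,31,33,30,11,14,31,24,33,51,81,26,11,38,17,44,16
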