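LABEL,ID,TRACK_ID,QUALITY,POSITION_X,POSITION_Y,POSITION_Z,POSITION_T,FRAME,RADIUS,VISIBILITY,MEAN_INTENSITY_CH1
Label,Spot ID,Track ID,Quality,X,Y,Z,T,Frame,Radius,Visibility,Mean intensity ch1
Label,Spot ID,Track ID,Quality,(pixel),(pixel),(pixel),(frame),,(pixel),,(counts)
ID1000,1000,0,31.5,120.25,88.75,0,0,0,5.0,1,183.2
ID1001,1001,0,30.9,122.10,90.40,0,90,1,5.0,1,180.1
ID1002,1002,0,29.4,124.80,92.00,0,180,2,5.0,1,178.9
ID2000,2000,1,28.8,40.00,200.50,0,0,0,5.0,1,190.4
ID2001,2001,1,27.2,38.60,198.90,0,90,1,5.0,1,188.8
ID2002,2002,1,26.9,36.90,197.10,0,180,2,5.0,1,186.3
ID2003,2003,1,25.5,35.10,195.00,0,270,3,5.0,1,184.0
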