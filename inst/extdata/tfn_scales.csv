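scale_id,point,lower,mode,upper
monthly6,1,0,0,30
monthly6,2,5,20,35
monthly6,3,25,40,55
monthly6,4,45,60,75
monthly6,5,65,80,95
monthly6,6,70,100,100
daily6,1,0,0,30
daily6,2,5,20,35
daily6,3,25,40,55
daily6,4,45,60,75
daily6,5,65,80,95
daily6,6,70,100,100
weekly8,1,0,0,25
weekly8,2,5,15,25
weekly8,3,20,30,40
weekly8,4,35,45,55
weekly8,5,45,55,65
weekly8,6,60,70,80
weekly8,7,75,85,95
weekly8,8,75,100,100
sitting10,1,0,0,10
sitting10,2,0,10,20
sitting10,3,10,20,30
sitting10,4,20,30,40
sitting10,5,27.5,40,52.5
sitting10,6,47.5,60,72.5
sitting10,7,60,70,80
sitting10,8,70,80,90
sitting10,9,80,90,100
sitting10,10,90,100,100
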