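name,h_lo,s_lo,v_lo,h_hi,s_hi,v_hi,eval_order
red,0,53,46,10,255,255,4
red,146,53,46,180,255,255,5
yellow,11,46,53,36,255,255,6
green,37,46,53,83,255,255,7
blue,84,53,46,124,255,255,8
purple,125,53,46,145,255,255,9
gray,0,0,71,180,25,229,3
black,0,0,0,180,255,70,1
white,0,0,230,180,30,255,2
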