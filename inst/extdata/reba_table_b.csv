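# REBA table B (upper arm x lower arm x wrist) lookup table, transcribed from Hignett S, McAtamney L (2000)
# "Rapid Entire Body Assessment (REBA)", Applied Ergonomics 31(2):201-205.
# Long format: one row per index combination.
upper_arm,lower_arm,wrist,score
1,1,1,1
2,1,1,1
3,1,1,3
4,1,1,4
5,1,1,6
6,1,1,7
1,2,1,1
2,2,1,2
3,2,1,4
4,2,1,5
5,2,1,8
6,2,1,8
1,1,2,2
2,1,2,2
3,1,2,4
4,1,2,5
5,1,2,7
6,1,2,8
1,2,2,2
2,2,2,3
3,2,2,5
4,2,2,6
5,2,2,8
6,2,2,9
1,1,3,2
2,1,3,3
3,1,3,5
4,1,3,5
5,1,3,8
6,1,3,8
1,2,3,3
2,2,3,4
3,2,3,5
4,2,3,7
5,2,3,8
6,2,3,9
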