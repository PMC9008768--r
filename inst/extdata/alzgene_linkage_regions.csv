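chr,band,start_mb,end_mb
1,p31.1-q31.1,83,185
3,q12.3-q25.31,103,173
6,p21.1-q15,43,91
7,pter-q21.11,0,78
8,p22-p21.1,13,28
9,p22.3-p13.3,20,35
9,q21.31-q32,80,100
10,p14-q24,10,100
17,q24.3-qter,67,79
19,p13.3-qter,8,54
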