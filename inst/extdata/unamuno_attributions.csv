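segment,n,category,proportion,flag,note
1,10,Se,0.50,none,
1,10,Pr,0.60,high,
1,10,Em,0.30,low,
1,10,Th,0.30,low,
1,10,Im,0.60,high,
1,10,Re,0.70,high,
1,10,In,0.20,low,
2,14,Se,0.57,none,
2,14,Pr,0.21,low,
2,14,Em,0.36,none,
2,14,Th,0.36,none,
2,14,Im,0.00,low,
2,14,Re,0.14,low,
2,14,In,0.29,low,
3,16,Se,0.13,low,
3,16,Pr,0.19,low,
3,16,Em,0.25,low,
3,16,Th,0.69,high,
3,16,Im,0.00,low,
3,16,Re,0.00,low,
3,16,In,0.31,low,
4,16,Se,0.13,low,
4,16,Pr,0.06,low,
4,16,Em,0.06,low,
4,16,Th,0.81,high,
4,16,Im,0.00,low,
4,16,Re,0.00,low,
4,16,In,0.19,low,
5,15,Se,0.27,low,
5,15,Pr,0.40,none,ambiguous printed markup; not significant per prose summary
5,15,Em,0.13,low,
5,15,Th,0.27,low,
5,15,Im,0.27,low,
5,15,Re,0.27,low,
5,15,In,0.27,low,
6,16,Se,0.50,none,
6,16,Pr,0.25,low,
6,16,Em,0.13,low,
6,16,Th,0.37,none,
6,16,Im,0.19,low,
6,16,Re,0.13,low,
6,16,In,0.25,low,
7,11,Se,0.27,low,
7,11,Pr,0.00,low,
7,11,Em,0.82,high,
7,11,Th,0.00,low,
7,11,Im,0.00,low,
7,11,Re,0.00,low,
7,11,In,0.72,high,
8,16,Se,0.38,none,
8,16,Pr,0.06,low,
8,16,Em,1.00,high,
8,16,Th,0.06,low,
8,16,Im,0.06,low,
8,16,Re,0.06,low,
8,16,In,0.90,high,
9,16,Se,0.25,low,
9,16,Pr,0.06,low,
9,16,Em,0.69,high,
9,16,Th,0.82,high,
9,16,Im,0.19,low,
9,16,Re,0.06,low,
9,16,In,0.25,low,
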