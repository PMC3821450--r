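line,index,starred,translation
1,0.375,0,"The most insignificant occurrence"
2,0.5,0,"any sentence I encounter,"
3,0.25,0,"the most innocent word I hear,"
4,0.625,1,"whatever my son says,"
5,0.125,0,"everything seems to me a signal, a symbol"
6,0.813,1,"and a matter of hidden meaning,"
7,1.0,1,"I translate everything to my state."
8,1.0,1,"If I continue like this I will fall into superstition."
9,0.063,0,"Not a single bell tolls"
10,0.934,1,"that I fail to believe is calling me;"
11,0.125,0,"I fancy that every man of the cloth that I pass"
12,1.0,1,"will approach to inquire what is the matter with me."
13,0.688,1,"A great desire to declare my state to all,"
14,1.0,1,"a great happiness to make confessions to anyone,"
15,0.125,0,"and a great dryness and indifference"
16,1.0,1,"if I think to do it as the Church commands."
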