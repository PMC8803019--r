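"id","sector"
1,"IN"
2,"IN"
3,"IN"
4,"IN"
5,"IT"
6,"IT"
7,"IT"
8,"IT"
9,"IN"
10,"IN"
11,"IT"
12,"IT"
13,"IT"
14,"IT"
15,"IT"
16,"IT"
17,"IN"
18,"N"
19,"IT"
20,"IT"
21,"IT"
22,"T"
23,"T"
24,"T"
25,"T"
26,"N"
27,"ST"
28,"ST"
29,"ST"
30,"ST"
31,"T"
32,"T"
33,"T"
34,"N"
35,"ST"
36,"ST"
37,"ST"
38,"ST"
39,"ST"
40,"ST"
41,"SN"
42,"N"
43,"ST"
44,"ST"
45,"ST"
46,"ST"
47,"SN"
48,"SN"
49,"SN"
50,"SN"
51,"SN"
52,"SN"
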