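no,manual,predicted
1,109,108
2,199,191
3,133,132
4,205,208
5,172,165
6,276,268
7,206,210
8,140,145
9,187,180
10,169,173
11,104,109
12,187,193
13,127,133
14,165,154
15,160,154
16,250,229
17,343,334
18,226,215
19,210,202
20,186,181
21,225,217
22,164,154
23,166,159
24,98,104
25,276,252
26,183,171
27,98,99
28,220,215
29,174,173
30,113,118
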