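dose	response
0.5	0.0817
1	0.0436
2	0.1061
5	0.2168
10	0.2982
20	0.3811
50	0.4886
100	0.5023
300	0.5307
1000	0.58
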