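name	tb161
half_life_d	6.89
[beta]
593.7	0.238	66	allowed
568	0.009	66	allowed
519.1	0.663	66	allowed
175.9	0.09	66	allowed
[discrete]
0.35	4.423	auger
1	5.182	auger
4.8	1.05	auger
16.7	0.74	conversion
20.8	0.62	conversion
23.6	0.28	conversion
49.3	0.065	conversion
65.5	0.013	conversion
72.6	0.007	conversion
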