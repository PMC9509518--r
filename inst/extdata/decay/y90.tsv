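name	y90
half_life_d	2.67
[beta]
2278.5	0.999988	40	first_forbidden_unique
518.6	0.000012	40	allowed
[discrete]
1.7	0.00092	auger
11.5	0.00035	auger
1743.9	0.000115	conversion
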