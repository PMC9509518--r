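name	lu177
half_life_d	6.65
[beta]
498.3	0.794	72	allowed
385.3	0.09	72	allowed
177	0.116	72	allowed
[discrete]
0.67	0.98	auger
5.1	0.11	auger
47.6	0.08	conversion
61.2	0.028	conversion
101.9	0.046	conversion
110.7	0.012	conversion
142.6	0.008	conversion
197.7	0.004	conversion
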