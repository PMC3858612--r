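dyad	neutral	agonistic	affiliative	total
m10f1B	0.12	0.02	0.00	0.15
m9f2	0.24	0.03	0.01	0.28
m3f3	0.09	0.04	0.00	0.13
m4f4	0.07	0.02	0.00	0.10
m5f5	0.05	0.00	0.00	0.05
m6f6	0.12	0.05	0.00	0.17
m7f7	0.07	0.05	0.00	0.12
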