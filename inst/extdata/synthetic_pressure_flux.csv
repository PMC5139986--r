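Pa,flow
75,0.80563
77,0.79013
79,0.78467
81,0.85219
83,0.81144
85,0.84405
87,0.88684
89,0.89633
91,0.927
93,0.94149
95,0.91608
97,0.98463
99,0.99238
101,0.9927
103,0.98175
105,1.09768
107,1.06775
109,1.04816
111,1.12648
113,1.12984
115,1.159
117,1.16812
119,1.17869
121,1.16702
123,1.2015
125,1.23315
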