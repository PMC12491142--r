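"depth_cm","slope","amplitude"
2,0.468793329760737,1
4,0.441482084591162,1
6,0.41758001150891,1
8,0.396661554877508,1
10,0.378354279758148,1
12,0.362332241029305,1
14,0.34831018021715,1
16,0.336038446716353,1
18,0.325298552978051,1
20,0.315899284528932,1
22,0.307673295563741,1
24,0.300474129498664,1
26,0.294173611439149,1
28,0.288659566137314,1
30,0.283833820809153,1
32,0.279610457253451,1
34,0.275914282152882,1
36,0.272679488322353,1
38,0.26984848306927,1
40,0.2673708628057,1
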