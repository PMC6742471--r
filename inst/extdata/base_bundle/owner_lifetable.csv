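"age","q_annual"
40,0.0015157165665104
41,0.00162450479271247
42,0.00174110112659225
43,0.00186606598307361
44,0.002
45,0.00214354692507259
46,0.00229739670999407
47,0.00246228882668983
48,0.00263901582154579
49,0.00282842712474619
50,0.0030314331330208
51,0.00324900958542494
52,0.0034822022531845
53,0.00373213196614723
54,0.004
55,0.00428709385014517
56,0.00459479341998814
57,0.00492457765337966
58,0.00527803164309158
59,0.00565685424949238
60,0.00606286626604159
61,0.00649801917084988
62,0.00696440450636899
63,0.00746426393229446
64,0.008
65,0.00857418770029035
66,0.00918958683997628
67,0.00984915530675933
68,0.0105560632861832
69,0.0113137084989848
70,0.0121257325320832
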