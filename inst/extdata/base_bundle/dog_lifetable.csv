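"dog_age","q_annual"
2,0.00285232114081737
3,0.00404763636910042
4,0.00574386941989625
5,0.00815093869713195
6,0.0115667325956729
7,0.0164139748697753
8,0.0232925390811234
9,0.0330536863343624
10,0.0469054136384742
11,0.0665619503477023
12,0.0944559037094999
13,0.134039307727201
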