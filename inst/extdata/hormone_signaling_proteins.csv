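ko_id,name,fold_change,p_value,regulation,pathway
K14508,NPR1,1.401,0.001,Up,Salicylic acid
K14493,GID1,0.816,0.018,Down,Gibberellin
K07513,ACAA1,1.480,0.001,Up,Jasmonic acid
K15718,LOX1_5,1.471,0.025,Up,Jasmonic acid
K15718,LOX1_5,1.308,0.046,Up,Jasmonic acid
K00454,LOX2S,1.254,0.001,Up,Jasmonic acid
K10528,HPL,1.371,0.011,Up,Jasmonic acid
K10525,AOC,0.740,0.015,Down,Jasmonic acid
K01723,AOS,0.788,0.000,Down,Jasmonic acid
K01723,AOS,0.772,0.000,Down,Jasmonic acid
K00128,ALDH,0.726,0.006,Down,Indole-3-acetic acid
K00128,ALDH,0.719,0.024,Down,Indole-3-acetic acid
K14085,ALDH7A1,0.595,0.000,Down,Indole-3-acetic acid
K14085,ALDH7A1,0.550,0.003,Down,Indole-3-acetic acid
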