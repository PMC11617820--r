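sample,medium,duration_s,load_ng_cm2,release_ng_cm2,family
AgCurA,abrasion-sweat,10,849,17.6,AgCur
AgCurB,abrasion-sweat,10,1444,12.6,AgCur
AgCurC,abrasion-sweat,10,1530,19.1,AgCur
AgCurC(P),abrasion-sweat,10,1147,17.9,AgCur
AgCurD,abrasion-sweat,10,1957,27.6,AgCur
AgCurE,abrasion-sweat,10,2258,31.7,AgCur
AgHEC6.4A,abrasion-sweat,10,1149,25,AgHEC6.4
AgHEC6.4B,abrasion-sweat,10,1222,33.1,AgHEC6.4
AgHEC6.4C,abrasion-sweat,10,1538,34.1,AgHEC6.4
AgHEC6.4C(P),abrasion-sweat,10,1529,16.4,AgHEC6.4
AgHEC6.4D,abrasion-sweat,10,1861,40.7,AgHEC6.4
AgHEC6.4E,abrasion-sweat,10,2651,47.3,AgHEC6.4
AgHECC,abrasion-sweat,10,1311,35.9,AgHEC
AgHECC(P),abrasion-sweat,10,1406,23.3,AgHEC
AgHECD,abrasion-sweat,10,1574,49.7,AgHEC
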