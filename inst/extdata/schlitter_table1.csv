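potential,water,s_holo_jmolk,s_apo_jmolk,temperature_k
CGenFF 4.1,TIP3P,392,439,300.15
GAFF 1.81,TIP3P,458,643,300.15
GAFF 1.81,OPC3,465,641,300.15
GAFF 2.11,TIP3P,364,417,300.15
GAFF 2.11,OPC3,364,427,300.15
GAFF 2.1,TIP3P,340,385,298
GAFF 2.1 sugar-specific dih.,TIP3P,370,445,298
GAFF 2.1 both dih. sets,TIP3P,389,495,298
GAFF 2.1 both dih. sets PREMD,TIP3P,391,535,298
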