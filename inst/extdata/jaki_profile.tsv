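# JAK 1,2,3 inhibitor (tofacitinib / upadacitinib / filgotinib class)
# target profile.
protein	effect_sign	is_pseudotarget
JAK1	down	FALSE
JAK2	down	FALSE
JAK3	down	FALSE
TYK2	down	FALSE
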