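# Vedolizumab target profile. MADCAM1 is a pseudotarget: the drug does not
# bind it, but clamping it represents the blocked integrin-MAdCAM-1
# interaction and gives the model a downstream route into the tissue.
protein	effect_sign	is_pseudotarget
ITGA4	down	FALSE
ITGB7	down	FALSE
MADCAM1	down	TRUE
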