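trait,environment,h2
DF,nursery,0.67
DF,winter_nursery,0.68
DF,field,0.92
WM,nursery,0.33
WM,winter_nursery,0.65
WM,field,0.78
SY,nursery,0.21
SY,winter_nursery,0.29
SY,field,0.70
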