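# example detector geometry (flat key = value format)
label = waxs
energy_keV = 13.5
distance_mm = 300
beam_center = 0 0
pixel_size_mm = 0.172
shape = 195 487
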