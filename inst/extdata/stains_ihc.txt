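# Stain optical-density vectors: name r g b (unit-normalised on read).
# Haematoxylin and DAB: Ruifrok-Johnston values.
haematoxylin 0.650 0.704 0.286
dab 0.268 0.570 0.776
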