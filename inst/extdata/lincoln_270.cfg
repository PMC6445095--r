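# NZ soil profile: 270 mm plant-available water over 30 x 5 cm layers
name = Lincoln
total_awc = 270
n_layers = 30
lambda_top = 0.10
lambda_bottom = 0.04
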