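# UK soil profile: 210 mm plant-available water over 30 x 5 cm layers
name = Rothamsted
total_awc = 210
n_layers = 30
lambda_top = 0.10
lambda_bottom = 0.04
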