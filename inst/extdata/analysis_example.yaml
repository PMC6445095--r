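# Example analysis configuration: reduced run sizes for a quick desk run.
# Omitted keys take the package defaults (the full study settings).
seed: 17
easa:
  n_years: 25
  max_generations: 30
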