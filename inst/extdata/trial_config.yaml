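rate_N_kg_ha: 90
rate_P_kg_ha: 50
rate_K_kg_ha: 75
plant_density_ha: 20000
n_blocks: 4
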