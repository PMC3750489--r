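quantity	value
regulators	19
transporter_genes	86
enzymes	127
total_genes	241
regulon_genes	181
tf_binding_sites	40
target_genes	163
network_tfs	18
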