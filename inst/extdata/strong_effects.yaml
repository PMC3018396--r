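# Strong-effects synthetic study conditions: 2000 proteins, yeast-like
# class mix, class-conditional effects strong enough that the residue
# concentration contrast between classes exceeds 5x.
"n": 2000
degree_exponent: 2.5
hub_threshold: 9
nonhub_threshold: 3
pcc_threshold: 0.5
effect: 2.5
mix: [0.814, 0.098, 0.033, 0.055]
domain_vocab_size: 60
with_pssm: true
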