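# note: protein-to-MAG assignment for the synthetic example
protein_id	mag_id
P001	MAG_A
P002	MAG_A
P003	MAG_B
P004	unbinned
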