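# units: counts spectra per injection
# note: synthetic example matching example_proteins.faa; P004 is a single-peptide contaminant
protein_id	unique_peptides	inj_1	inj_2	inj_3	inj_4
P001	12	420	395	0	410
P002	8	210	180	205	0
P003	5	95	110	90	105
P004	1	40	35	38	42
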